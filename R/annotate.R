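#' Impact tier of an effect term
#'
#' Fixed total mapping from sequence-ontology-style effect terms to the
#' HIGH / MODERATE / LOW / MODIFIER tiers used by annotation tools of the
#' SnpEff family: HIGH for truncating or splice-disrupting changes, MODERATE
#' for protein-altering non-truncating changes, LOW for silent coding or
#' near-splice changes, MODIFIER for everything non-coding.
#'
#' @param effect character vector of effect terms
#' @return character vector of impact tiers
#' @export
impact_of <- function(effect) {
  high <- c("stop_gained", "stop_lost", "start_lost",
            "splice_acceptor_variant", "splice_donor_variant",
            "frameshift_variant")
  moderate <- c("missense_variant", "inframe_insertion", "inframe_deletion")
  low <- c("synonymous_variant", "splice_region_variant",
           "stop_retained_variant", "start_retained_variant",
           "utr_premature_start_gain")
  ifelse(effect %in% high, "HIGH",
         ifelse(effect %in% moderate, "MODERATE",
                ifelse(effect %in% low, "LOW", "MODIFIER")))
}

impact_rank <- function(impact)
  match(impact, c("HIGH", "MODERATE", "LOW", "MODIFIER"))

# Deterministic priority among effects of equal impact (coding before
# splice-region before UTR/regional terms).
effect_priority <- c(
  "stop_gained", "stop_lost", "start_lost", "frameshift_variant",
  "splice_acceptor_variant", "splice_donor_variant",
  "missense_variant", "inframe_insertion", "inframe_deletion",
  "synonymous_variant", "stop_retained_variant", "start_retained_variant",
  "utr_premature_start_gain", "splice_region_variant",
  "5_prime_UTR_variant", "3_prime_UTR_variant",
  "non_coding_transcript_exon_variant", "intron_variant",
  "upstream_gene_variant", "downstream_gene_variant", "intergenic_variant"
)

# Splice-window geometry (annotation-tool family conventions): the first and
# last 2 intronic bases are donor/acceptor sites (HIGH, by transcription
# orientation); intronic bases 3-8 from a junction and the 3 exonic bases
# flanking a junction are splice region (LOW).
splice_donor_len <- 2L
splice_region_intron <- 8L
splice_region_exon <- 3L

#' Classify the genomic region of a variant
#'
#' Region precedence within a gene: splice site region over (CDS) exon over
#' UTR over intron; outside every gene span but within `flank` bp a variant
#' is upstream or downstream by strand; otherwise intergenic. A variant
#' overlapping two genes yields one classification per gene (use
#' [annotate_variants()] for the full table).
#'
#' @param chrom,pos variant position (1-based)
#' @param genes a `gene_models` object
#' @param flank flanking distance in bp (default 5000)
#' @return data.frame: `gene_id` (`NA` for intergenic), `region`
#' @export
classify_region <- function(chrom, pos, genes, flank = 5000) {
  hits <- gene_hits(genes, chrom, pos, pos, flank)
  if (!nrow(hits))
    return(data.frame(gene_id = NA_character_, region = "intergenic",
                      stringsAsFactors = FALSE))
  out <- lapply(seq_len(nrow(hits)), function(i) {
    m <- genes$models[[hits$model_idx[i]]]
    data.frame(gene_id = m$gene_id,
               region = region_in_gene(m, pos),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# All gene models whose span+flank overlaps [pos1, pos2] (1-based inclusive).
gene_hits <- function(genes, chrom, pos1, pos2, flank) {
  idx <- genes$index
  sel <- which(idx$chrom == chrom &
                 pos2 > idx$start - flank & pos1 <= idx$end + flank)
  data.frame(model_idx = sel)
}

# Region class of a single base within (or near) one gene model.
region_in_gene <- function(m, pos) {
  p0 <- pos - 1                                  # 0-based
  if (p0 < m$start || p0 >= m$end) {             # flank
    before <- p0 < m$start
    if (m$strand == "+") return(if (before) "upstream" else "downstream")
    return(if (before) "downstream" else "upstream")
  }
  spl <- splice_class(m, pos)
  if (!is.na(spl)) return("splice_site_region")
  if (in_intervals(p0, m$cds)) return("exon")
  if (in_intervals(p0, m$utr5)) return("utr5")
  if (in_intervals(p0, m$utr3)) return("utr3")
  if (in_intervals(p0, m$exons)) return("exon")  # non-coding exon
  "intron"
}

in_intervals <- function(p0, iv)
  nrow(iv) > 0 && any(p0 >= iv[, 1] & p0 < iv[, 2])

# Splice classification of a base relative to a gene's exon junctions:
# returns "splice_donor_variant", "splice_acceptor_variant",
# "splice_region_variant" or NA. Intronic windows only for donor/acceptor;
# the exonic splice-region flank is reported by splice_class_exonic().
splice_class <- function(m, pos) {
  p0 <- pos - 1
  ex <- m$exons
  if (nrow(ex) < 2) return(NA_character_)
  for (k in seq_len(nrow(ex) - 1)) {
    int_s <- ex[k, 2]; int_e <- ex[k + 1, 1]    # intron, 0-based half-open
    if (p0 < int_s || p0 >= int_e) next
    d_left <- p0 - int_s + 1                     # 1 = first intron base (left)
    d_right <- int_e - p0                        # 1 = last intron base (right)
    left_is_donor <- m$strand == "+"
    if (d_left <= splice_donor_len)
      return(if (left_is_donor) "splice_donor_variant" else "splice_acceptor_variant")
    if (d_right <= splice_donor_len)
      return(if (left_is_donor) "splice_acceptor_variant" else "splice_donor_variant")
    if (d_left <= splice_region_intron || d_right <= splice_region_intron)
      return("splice_region_variant")
    return(NA_character_)
  }
  NA_character_
}

# TRUE when an exonic base lies within splice_region_exon bases of an
# internal exon junction.
splice_class_exonic <- function(m, pos) {
  p0 <- pos - 1
  ex <- m$exons
  if (nrow(ex) < 2) return(FALSE)
  for (k in seq_len(nrow(ex))) {
    if (p0 < ex[k, 1] || p0 >= ex[k, 2]) next
    near_end <- k < nrow(ex) && (ex[k, 2] - p0) <= splice_region_exon
    near_start <- k > 1 && (p0 - ex[k, 1] + 1) <= splice_region_exon
    return(near_end || near_start)
  }
  FALSE
}

#' Predicted coding effect of a variant within one gene
#'
#' For a SNP overlapping the CDS, rebuilds the affected codon on the coding
#' strand, translates with the standard nuclear code and classifies
#' synonymous / missense / stop_gained / stop_lost / start_lost (start codon
#' ATG only). For an indel in the CDS: length difference not divisible by 3
#' gives frameshift_variant, otherwise inframe_insertion / inframe_deletion.
#' The reference allele must match the genome at the site.
#'
#' @param chrom,pos,ref,alt the variant (1-based position, VCF alleles)
#' @param gene one gene model (element of `gene_models$models`)
#' @param ref_genome a [read_fasta()] genome
#' @return effect term (character scalar)
#' @export
classify_coding_effect <- function(chrom, pos, ref, alt, gene, ref_genome) {
  if (!gene$coding) stop("gene ", gene$gene_id, " is non-coding")
  genome_ref <- fetch_seq(ref_genome, chrom, pos, pos + nchar(ref) - 1)
  if (genome_ref != ref)
    stop(sprintf("reference mismatch at %s:%d: VCF %s, genome %s",
                 chrom, pos, ref, genome_ref))
  if (nchar(ref) != nchar(alt)) {
    dlen <- abs(nchar(ref) - nchar(alt))
    if (dlen %% 3 != 0) return("frameshift_variant")
    return(if (nchar(alt) > nchar(ref)) "inframe_insertion" else "inframe_deletion")
  }
  # SNP: locate the base in the spliced CDS
  cds_pos <- cds_offset(gene, pos)
  if (is.na(cds_pos)) stop("position not in CDS of ", gene$gene_id)
  cds_seq <- spliced_cds(gene, ref_genome)
  codon_i <- (cds_pos - 1) %/% 3 + 1
  n_codon <- nchar(cds_seq) %/% 3
  codon <- substr(cds_seq, 3 * codon_i - 2, 3 * codon_i)
  within <- (cds_pos - 1) %% 3 + 1
  base <- if (gene$strand == "+") alt else revcomp(alt)
  alt_codon <- codon
  substr(alt_codon, within, within) <- base
  aa_ref <- translate_codon(codon)
  aa_alt <- translate_codon(alt_codon)
  if (codon_i == 1 && codon == "ATG" && alt_codon != "ATG") return("start_lost")
  if (aa_ref == "*" && aa_alt == "*") return("stop_retained_variant")
  if (aa_ref == "*" && aa_alt != "*") return("stop_lost")
  if (aa_alt == "*") return("stop_gained")
  if (aa_ref == aa_alt) return("synonymous_variant")
  "missense_variant"
}

# 1-based offset of a genomic position within the spliced CDS (coding-strand
# orientation), NA if outside the CDS.
cds_offset <- function(gene, pos) {
  p0 <- pos - 1
  cds <- gene$cds
  if (!nrow(cds)) return(NA_integer_)
  lens <- cds[, 2] - cds[, 1]
  if (gene$strand == "+") {
    off <- 0
    for (k in seq_len(nrow(cds))) {
      if (p0 >= cds[k, 1] && p0 < cds[k, 2]) return(off + (p0 - cds[k, 1]) + 1)
      off <- off + lens[k]
    }
  } else {
    off <- 0
    for (k in rev(seq_len(nrow(cds)))) {
      if (p0 >= cds[k, 1] && p0 < cds[k, 2]) return(off + (cds[k, 2] - 1 - p0) + 1)
      off <- off + lens[k]
    }
  }
  NA_integer_
}

# Spliced CDS sequence on the coding strand.
spliced_cds <- function(gene, ref_genome) {
  segs <- vapply(seq_len(nrow(gene$cds)), function(k)
    fetch_seq(ref_genome, gene$chrom, gene$cds[k, 1] + 1, gene$cds[k, 2]),
    character(1))
  s <- paste(segs, collapse = "")
  if (gene$strand == "-") s <- revcomp(s)
  s
}

translate_codon <- function(codon) {
  if (nchar(codon) != 3 || grepl("[^ACGT]", codon)) return("X")
  unname(Biostrings::GENETIC_CODE[codon])
}

# 5'-UTR start-gain check: does the alt base create an ATG in any frame on
# the coding strand (within the reference context around the variant)?
utr5_start_gain <- function(chrom, pos, ref, alt, gene, ref_genome) {
  if (nchar(ref) != 1 || nchar(alt) != 1) return(FALSE)
  lens <- chrom_lengths(ref_genome)[[chrom]]
  lo <- max(1, pos - 2); hi <- min(lens, pos + 2)
  ctx <- fetch_seq(ref_genome, chrom, lo, hi)
  at <- pos - lo + 1
  substr(ctx, at, at) <- alt
  if (gene$strand == "-") {
    ctx <- revcomp(ctx)
  }
  grepl("ATG", ctx, fixed = TRUE) &&
    !grepl("ATG", {
      orig <- fetch_seq(ref_genome, chrom, lo, hi)
      if (gene$strand == "-") revcomp(orig) else orig
    }, fixed = TRUE)
}

#' Annotate all variants of a cohort
#'
#' Every retained variant receives one record per overlapping gene (or one
#' intergenic record), carrying the highest-impact effect among the
#' candidate effects at that position in that gene; the region class is
#' derived from the chosen effect (Table-2-style classes: intergenic, exon,
#' intron, splice site region, 5'/3'-UTR, plus upstream/downstream within
#' the flank). Also computes the cohort summary: region percentages, impact
#' counts overall and per sample group (a variant counts for a group when at
#' least one member carries a non-reference allele), the Ka/Ks change-count
#' ratio and the Ts/Tv ratio.
#'
#' @param x a filtered [cohort()]
#' @param genes a `gene_models` object
#' @param ref_genome a [read_fasta()] genome
#' @param flank upstream/downstream flank in bp (default 5000)
#' @param group_by metadata column defining the per-group summaries
#' @return list: `effects` (data.frame chrom, pos, ref, alt, gene_id,
#'   region, effect, impact), `summary` (an `annotation_summary` list)
#' @export
annotate_variants <- function(x, genes, ref_genome, flank = 5000,
                              group_by = "subspecies") {
  s <- x$sites
  alts1 <- vapply(strsplit(s$alt, ",", fixed = TRUE), `[`, character(1), 1)
  recs <- vector("list", nrow(s))
  for (i in seq_len(nrow(s))) {
    recs[[i]] <- annotate_one(s$chrom[i], s$pos[i], s$ref[i], alts1[i],
                              genes, ref_genome, flank)
  }
  effects <- do.call(rbind, recs)
  effects <- cbind(
    data.frame(chrom = rep(s$chrom, vapply(recs, nrow, integer(1))),
               pos = rep(s$pos, vapply(recs, nrow, integer(1))),
               ref = rep(s$ref, vapply(recs, nrow, integer(1))),
               alt = rep(alts1, vapply(recs, nrow, integer(1))),
               site_idx = rep(seq_len(nrow(s)), vapply(recs, nrow, integer(1))),
               stringsAsFactors = FALSE),
    effects)
  rownames(effects) <- NULL
  summary <- annotation_summary(x, effects, group_by)
  list(effects = effects, summary = summary)
}

# One variant against all overlapping genes: data.frame(gene_id, region,
# effect, impact), at least one row.
annotate_one <- function(chrom, pos, ref, alt, genes, ref_genome, flank) {
  hits <- gene_hits(genes, chrom, pos, pos + nchar(ref) - 1, flank)
  if (!nrow(hits))
    return(data.frame(gene_id = NA_character_, region = "intergenic",
                      effect = "intergenic_variant", impact = "MODIFIER",
                      stringsAsFactors = FALSE))
  out <- lapply(hits$model_idx, function(mi) {
    m <- genes$models[[mi]]
    eff <- best_effect(chrom, pos, ref, alt, m, ref_genome)
    data.frame(gene_id = m$gene_id, region = eff$region, effect = eff$effect,
               impact = impact_of(eff$effect), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Candidate effects of one variant in one gene; returns the highest-impact
# one (ties broken by the fixed effect priority) plus its region class.
best_effect <- function(chrom, pos, ref, alt, m, ref_genome) {
  p0 <- pos - 1
  ref_end0 <- p0 + nchar(ref)                    # half-open end of ref span
  cand <- character(0)
  in_span <- ref_end0 > m$start && p0 < m$end
  if (!in_span) {
    before <- ref_end0 <= m$start
    eff <- if ((before && m$strand == "+") || (!before && m$strand == "-"))
      "upstream_gene_variant" else "downstream_gene_variant"
    return(list(effect = eff,
                region = if (eff == "upstream_gene_variant") "upstream" else "downstream"))
  }
  is_snp <- nchar(ref) == 1 && nchar(alt) == 1
  overlaps <- function(iv) nrow(iv) > 0 &&
    any(ref_end0 > iv[, 1] & p0 < iv[, 2])
  in_cds <- m$coding && overlaps(m$cds)
  if (in_cds) {
    cand <- c(cand, classify_coding_effect(chrom, pos, ref, alt, m, ref_genome))
  }
  if (is_snp) {
    spl <- splice_class(m, pos)
    if (!is.na(spl)) cand <- c(cand, spl)
    else if (splice_class_exonic(m, pos) && overlaps(m$exons))
      cand <- c(cand, "splice_region_variant")
  }
  if (overlaps(m$utr5)) {
    if (is_snp && utr5_start_gain(chrom, pos, ref, alt, m, ref_genome))
      cand <- c(cand, "utr_premature_start_gain")
    cand <- c(cand, "5_prime_UTR_variant")
  }
  if (overlaps(m$utr3)) cand <- c(cand, "3_prime_UTR_variant")
  if (!m$coding && overlaps(m$exons))
    cand <- c(cand, "non_coding_transcript_exon_variant")
  if (!length(cand)) cand <- "intron_variant"
  ord <- order(impact_rank(impact_of(cand)), match(cand, effect_priority))
  eff <- cand[ord[1]]
  list(effect = eff, region = region_of_effect(eff))
}

region_of_effect <- function(eff) {
  switch(eff,
         splice_acceptor_variant = ,
         splice_donor_variant = ,
         splice_region_variant = "splice_site_region",
         `5_prime_UTR_variant` = ,
         utr_premature_start_gain = "utr5",
         `3_prime_UTR_variant` = "utr3",
         intron_variant = "intron",
         upstream_gene_variant = "upstream",
         downstream_gene_variant = "downstream",
         intergenic_variant = "intergenic",
         non_coding_transcript_exon_variant = "exon",
         "exon")                                  # all coding effects
}

# Region/impact/Ka-Ks/Ts-Tv summary over an effect table.
annotation_summary <- function(x, effects, group_by = "subspecies") {
  # one primary record per variant: the highest-impact record
  prim <- effects[order(effects$site_idx, impact_rank(effects$impact),
                        match(effects$effect, effect_priority)), ]
  prim <- prim[!duplicated(prim$site_idx), ]
  region_counts <- table(factor(prim$region,
                                levels = c("intergenic", "exon", "intron",
                                           "splice_site_region", "utr5",
                                           "utr3", "upstream", "downstream")))
  impact_counts <- table(factor(prim$impact,
                                levels = c("HIGH", "MODERATE", "LOW", "MODIFIER")))
  n <- nrow(prim)
  ka <- sum(prim$effect %in% c("missense_variant", "stop_gained",
                               "stop_lost", "start_lost"))
  ks <- sum(prim$effect == "synonymous_variant")
  if (ks == 0 && ka > 0) warning("no synonymous changes: Ka/Ks undefined")

  carriers <- (x$gt_a > 0 & !is.na(x$gt_a)) | (x$gt_b > 0 & !is.na(x$gt_b))
  groups <- unique(x$samples[[group_by]])
  per_group <- lapply(groups, function(g) {
    gi <- which(x$samples[[group_by]] == g)
    has <- colSums(carriers[gi, , drop = FALSE]) > 0
    tab <- table(factor(prim$impact[has[prim$site_idx]],
                        levels = c("HIGH", "MODERATE", "LOW", "MODIFIER")))
    as.list(tab)
  })
  names(per_group) <- groups

  structure(list(
    n_variants = n,
    region_counts = as.list(region_counts),
    region_pct = as.list(100 * region_counts / n),
    impact_counts = as.list(impact_counts),
    impact_pct = as.list(100 * impact_counts / n),
    impact_by_group = per_group,
    ka_ks = if (ks > 0) ka / ks else NaN,
    ts_tv = ts_tv(x$sites)
  ), class = "annotation_summary")
}

#' Transition/transversion ratio
#'
#' Transitions are A<->G and C<->T; the ratio is over biallelic SNPs. `NaN`
#' (with a warning) when there are no transversions.
#'
#' @param sites a cohort site table (or data.frame with `ref`, `alt`,
#'   `is_snp`)
#' @return numeric ratio
#' @export
ts_tv <- function(sites) {
  if (is.null(sites$is_snp))
    sites$is_snp <- nchar(sites$ref) == 1 & nchar(sites$alt) == 1
  bi <- sites[sites$is_snp & !grepl(",", sites$alt), , drop = FALSE]
  if (!nrow(bi)) return(NaN)
  pair <- paste(pmin(bi$ref, bi$alt), pmax(bi$ref, bi$alt))
  is_ts <- pair %in% c("A G", "C T")
  n_tv <- sum(!is_ts)
  if (n_tv == 0) {
    warning("no transversions: Ts/Tv undefined")
    return(NaN)
  }
  sum(is_ts) / n_tv
}

#' Ka/Ks change-count ratio
#'
#' The genomic ratio of non-synonymous (missense, stop gained/lost, start
#' lost) to synonymous change counts — an unnormalized count ratio, not a
#' per-site dN/dS.
#'
#' @param effects effect table from [annotate_variants()]
#' @return numeric ratio (`NaN`, with a warning, when no synonymous changes)
#' @export
ka_ks <- function(effects) {
  prim <- effects[order(effects$site_idx, impact_rank(effects$impact)), ]
  prim <- prim[!duplicated(prim$site_idx), ]
  ka <- sum(prim$effect %in% c("missense_variant", "stop_gained",
                               "stop_lost", "start_lost"))
  ks <- sum(prim$effect == "synonymous_variant")
  if (ks == 0) {
    warning("no synonymous changes: Ka/Ks undefined")
    return(NaN)
  }
  ka / ks
}

#' Group-private effect-gene sets
#'
#' For each group of a sample partition, the set of genes carrying at least
#' one HIGH- or MODERATE-impact variant whose alternate allele is present in
#' the group and absent everywhere else, plus pairwise shared-and-exclusive
#' sets (alleles present in both groups of a pair and absent outside it) —
#' the set logic behind morphotype/subspecies comparisons.
#'
#' @param x a filtered [cohort()]
#' @param effects effect table from [annotate_variants()]
#' @param group_by metadata column (`"subspecies"`, `"morphotype"` or
#'   `"accession"`)
#' @return list: `private` (per group: gene vector), `private_counts`,
#'   `pairwise` (per pair: genes shared by the pair, absent elsewhere)
#' @export
gene_set_comparisons <- function(x, effects, group_by = "subspecies") {
  carriers <- (x$gt_a > 0 & !is.na(x$gt_a)) | (x$gt_b > 0 & !is.na(x$gt_b))
  groups <- unique(x$samples[[group_by]])
  pres <- vapply(groups, function(g) {
    gi <- which(x$samples[[group_by]] == g)
    colSums(carriers[gi, , drop = FALSE]) > 0
  }, logical(n_sites(x)))
  if (is.null(dim(pres))) pres <- matrix(pres, nrow = 1)
  colnames(pres) <- groups

  hm <- effects[effects$impact %in% c("HIGH", "MODERATE") &
                  !is.na(effects$gene_id), , drop = FALSE]
  private <- lapply(groups, function(g) {
    only <- pres[, g] & rowSums(pres[, setdiff(groups, g), drop = FALSE]) == 0
    sort(unique(hm$gene_id[only[hm$site_idx]]))
  })
  names(private) <- groups

  pairwise <- list()
  if (length(groups) > 2) {
    for (i in seq_len(length(groups) - 1)) {
      for (j in (i + 1):length(groups)) {
        g1 <- groups[i]; g2 <- groups[j]
        others <- setdiff(groups, c(g1, g2))
        both <- pres[, g1] & pres[, g2] &
          rowSums(pres[, others, drop = FALSE]) == 0
        pairwise[[paste(g1, g2, sep = "|")]] <-
          sort(unique(hm$gene_id[both[hm$site_idx]]))
      }
    }
  }
  list(private = private,
       private_counts = vapply(private, length, integer(1)),
       pairwise = pairwise,
       pairwise_counts = vapply(pairwise, length, integer(1)))
}
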