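#' Default accession panel
#'
#' Eight pooled accessions: five of subspecies *pepo* (Pumpkin, Vegetable
#' Marrow, Cocozelle, yellow and green Zucchini morphotypes) and three of
#' subspecies *ovifera* (Acorn, Crookneck, Scallop), each a pool of five
#' plants — the structure of the resequenced cohort the generator emulates.
#'
#' @return data.frame: `accession`, `morphotype`, `subspecies`, `pool_size`
#' @export
default_samples <- function() {
  data.frame(
    accession = c("Pumpkin", "Marrow", "Cocozelle", "Zucchini_yellow",
                  "Zucchini_green", "Acorn", "Crookneck", "Scallop"),
    morphotype = c("Pumpkin", "Vegetable-Marrow", "Cocozelle",
                   "Zucchini-yellow", "Zucchini-green",
                   "Acorn", "Crookneck", "Scallop"),
    subspecies = c(rep("pepo", 5), rep("ovifera", 3)),
    pool_size = 5L,
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' Defines a synthetic two-subspecies cohort: Balding-Nichols differentiation
#' between subspecies and drift among accessions, LD-block haplotype
#' structure within genomes, pooled-accession diploid calling with
#' depth/quality models and missingness, and planted features with known
#' truth (fixed-difference genes, high-diversity genes, group-private
#' HIGH/MODERATE effect variants, tri-allelic sites, high-missingness
#' sites).
#'
#' @param seed root seed; every component derives its own stream from it
#' @param n_chrom chromosomes (>= 2: background LD needs unlinked pairs)
#' @param chrom_len chromosome length in bp
#' @param n_sites total variant sites before planted additions
#' @param p_anc_range range of ancestral allele frequencies (uniform)
#' @param F_subspecies Balding-Nichols differentiation between subspecies
#' @param F_morphotype within-subspecies drift of accession frequencies
#' @param block_len LD block length (bp)
#' @param recomb_between_blocks backbone-switch probability per block border
#' @param freq_turnover probability per block border that the founder
#'   frequency is redrawn; sets the scale over which sites are statistically
#'   independent (expected segment length `block_len / freq_turnover`)
#' @param samples accession table (see [default_samples()])
#' @param depth_mean,depth_size negative-binomial read-depth model (DP)
#' @param depth_floor lower bound applied to sampled depths (0 = none); a
#'   floor at the masking threshold yields an all-confident cohort
#' @param gq_mean,gq_sd,gq_floor clamped-normal genotype-quality model (GQ)
#' @param missing_rate per-call probability of a missing genotype
#' @param pool_het_min pooled-call threshold: pooled alternate fraction f
#'   below this gives hom-ref, above 1 - f hom-alt, else het
#' @param ts_prob probability that a site's alternate allele is the
#'   transition partner of the reference (0.62 gives the Ts/Tv ratio near
#'   1.6 typical of plant resequencing panels)
#' @param genic_thinning probability of keeping a random site that falls in
#'   a gene span (< 1 thins genic SNPs, giving the negative gene-density /
#'   SNP-density association)
#' @param gene_len,gene_spacing gene span and tiling period (bp)
#' @param sites_per_planted_gene sites guaranteed inside each planted gene
#' @param n_fixed_genes planted fixed-difference genes (theta = 1)
#' @param n_high_pi_genes planted high-diversity genes
#' @param high_pi_group subspecies carrying the planted high diversity
#' @param n_private_high,n_private_moderate planted group-private effect
#'   variants (stop-gain / missense)
#' @param private_group_by,private_group sample partition and group owning
#'   the private variants
#' @param n_triallelic planted tri-allelic sites
#' @param n_high_missing planted sites exceeding 30% missing after masking
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1, n_chrom = 4, chrom_len = 500000,
                       n_sites = 20000, p_anc_range = c(0.05, 0.95),
                       F_subspecies = 0.1, F_morphotype = 0.05,
                       block_len = 10000, recomb_between_blocks = 0.02,
                       freq_turnover = 0.4,
                       samples = default_samples(),
                       depth_mean = 33, depth_size = 10, depth_floor = 0,
                       gq_mean = 60, gq_sd = 15, gq_floor = 0,
                       missing_rate = 0.02, pool_het_min = 0.15,
                       ts_prob = 0.62, genic_thinning = 0.8,
                       gene_len = 2000, gene_spacing = 5000,
                       sites_per_planted_gene = 5,
                       n_fixed_genes = 8, n_high_pi_genes = 5,
                       high_pi_group = "pepo",
                       n_private_high = 5, n_private_moderate = 5,
                       private_group_by = "subspecies",
                       private_group = "ovifera",
                       n_triallelic = 50, n_high_missing = 100) {
  stopifnot(n_chrom >= 2, F_subspecies > 0, F_subspecies < 1,
            F_morphotype > 0, F_morphotype < 1,
            gene_len < gene_spacing, chrom_len > gene_spacing)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Balding-Nichols population allele frequencies
#'
#' Draws population frequencies around ancestral frequencies `p_anc` from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`, so `E[p_pop] = p_anc` and
#' `Var[p_pop] = F p_anc (1 - p_anc)` — giving simulated populations a known
#' true differentiation `F`.
#'
#' @param p_anc ancestral frequency vector
#' @param F differentiation parameter in (0, 1); values below 1e-12 return
#'   `p_anc` (the zero-variance limit)
#' @return frequency vector of the same length
#' @export
balding_nichols_freqs <- function(p_anc, F) {
  stopifnot(all(p_anc >= 0 & p_anc <= 1), F >= 0, F < 1)
  if (F < 1e-12) return(p_anc)
  stats::rbeta(length(p_anc), p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
}

#' Simulate LD-block haplotypes
#'
#' Copying model: each haplotype carries one latent uniform backbone value
#' per LD block, redrawn at each block border with probability `recomb`;
#' within a block every site `s` gets allele `1` when the backbone value is
#' below the site frequency `p_s`. Marginal site frequencies are exact, all
#' frequency-matched sites within a block are perfectly correlated, and
#' between-block correlation decays geometrically with the number of block
#' borders crossed — a tunable LD-decay profile.
#'
#' @param n_hap haplotypes to draw
#' @param pos site positions (1-based, one chromosome, ascending)
#' @param freqs per-site allele-1 frequency, same length as `pos`
#' @param block_len block length (bp)
#' @param recomb switch probability per block border
#' @return integer matrix `n_hap` x `length(pos)` of 0/1 alleles
#' @export
simulate_haplotypes <- function(n_hap, pos, freqs, block_len, recomb) {
  stopifnot(length(pos) == length(freqs), !is.unsorted(pos))
  bidx <- (pos - 1) %/% block_len + 1L
  nb <- max(bidx)
  U <- matrix(0, nb, n_hap)
  U[1, ] <- stats::runif(n_hap)
  if (nb > 1) for (k in 2:nb) {
    sw <- stats::runif(n_hap) < recomb
    U[k, ] <- ifelse(sw, stats::runif(n_hap), U[k - 1, ])
  }
  A <- U[bidx, , drop = FALSE] < freqs        # recycles freqs down columns
  t(A) + 0L
}

#' Pooled-accession diploid calls
#'
#' Emulates calling one diploid genotype from a pool of plants: given the
#' pooled alternate-allele fraction `f` (over `2 x pool_size` alleles), the
#' emitted call is hom-ref when `f < pool_het_min`, hom-alt when
#' `f > 1 - pool_het_min`, and het otherwise — reproducing the excess
#' apparent heterozygosity of pooled calling.
#'
#' @param f pooled alternate fraction vector
#' @param pool_het_min het-call threshold (default 0.15)
#' @return list of integer vectors `a`, `b` (allele indexes)
#' @export
pool_calls <- function(f, pool_het_min = 0.15) {
  a <- integer(length(f))
  b <- integer(length(f))
  homalt <- f > 1 - pool_het_min
  het <- !homalt & f >= pool_het_min
  a[homalt] <- 1L
  b[homalt | het] <- 1L
  list(a = a, b = b)
}

#' Neutral coalescent sample of segregating sites
#'
#' Standard neutral coalescent without recombination for `n` sequences:
#' exponential coalescence times while `k` lineages remain (rate
#' `k (k - 1) / 2`), Poisson mutations on branches at rate `theta / 2` per
#' unit time, infinite-sites output. Returns the derived-allele count of
#' every segregating site — the null input for Tajima's D.
#'
#' @param n sample size (sequences)
#' @param theta population mutation rate (`4 N mu` per locus)
#' @return integer vector of derived counts (possibly empty), with
#'   attribute `tree_length` (total branch length)
#' @export
hudson_coalescent <- function(n, theta) {
  stopifnot(n >= 2, theta >= 0)
  leaves <- rep(1L, n)            # descendant leaves per active lineage
  counts <- integer(0)
  total_len <- 0
  k <- n
  while (k > 1) {
    t_k <- stats::rexp(1, rate = k * (k - 1) / 2)
    total_len <- total_len + k * t_k
    n_mut <- stats::rpois(k, theta / 2 * t_k)
    counts <- c(counts, rep(leaves, n_mut))
    pair <- sample.int(k, 2)
    leaves <- c(leaves[-pair], leaves[pair[1]] + leaves[pair[2]])
    k <- k - 1L
  }
  structure(counts[counts < n], tree_length = total_len)
}

# ---- cohort generation -----------------------------------------------------

#' Simulate a synthetic two-subspecies cohort
#'
#' Builds the full in-memory bundle: random reference genome with tiled
#' gene models (exon/intron/UTR structure, start and stop codons in place),
#' Balding-Nichols site frequencies with accession-level drift, LD-block
#' plant haplotypes pooled into accession calls with depth/quality and
#' missingness, and every planted feature of the configuration, plus a
#' machine-readable truth record. [emit_cohort()] writes the same bundle to
#' FASTA / GFF3 / VCF / TSV / JSON files.
#'
#' @param config a [sim_config()]
#' @return list: `cohort` (raw, pre-masking), `genes`, `ref`, `meta`,
#'   `truth`
#' @export
simulate_cohort <- function(config) {
  cfg <- config
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  n_samp <- nrow(cfg$samples)

  # reference genome
  genome <- with_seed(child_seed(cfg$seed, "genome"), {
    stats::setNames(vapply(chroms, function(ch)
      paste(sample(c("A", "C", "G", "T"), cfg$chrom_len, replace = TRUE),
            collapse = ""), character(1)), chroms)
  })

  # gene tiling: alternate strands, fixed internal structure
  genes_per_chrom <- (cfg$chrom_len - 1000) %/% cfg$gene_spacing
  gl <- cfg$gene_len
  e1 <- round(gl * 0.3); i1 <- round(gl * 0.5)   # exon1 [0,e1), exon2 [i1,gl)
  u5 <- round(gl * 0.075)                        # CDS starts at u5
  cds2_end <- gl - ((e1 - u5) + (gl - i1)) %% 3  # make CDS length %% 3 == 0
  build_gene <- function(ch, g, strand) {
    s0 <- (g - 1) * cfg$gene_spacing + 1000
    list(gene_id = sprintf("%s_g%03d", ch, g),
         transcript_id = sprintf("%s_g%03d.1", ch, g),
         chrom = ch, strand = strand, start = s0, end = s0 + gl,
         exons = rbind(c(s0, s0 + e1), c(s0 + i1, s0 + gl)),
         cds = rbind(c(s0 + u5, s0 + e1), c(s0 + i1, s0 + cds2_end)),
         utr5 = NULL, utr3 = NULL, coding = TRUE)
  }
  models <- list()
  for (ch in chroms) for (g in seq_len(genes_per_chrom)) {
    strand <- if ((g %% 2) == 1) "+" else "-"
    m <- build_gene(ch, g, strand)
    utr <- interval_diff(m$exons, m$cds)
    lo <- min(m$cds[, 1]); hi <- max(m$cds[, 2])
    before <- utr[utr[, 1] < lo, , drop = FALSE]
    after <- utr[utr[, 1] >= hi, , drop = FALSE]
    if (strand == "+") { m$utr5 <- before; m$utr3 <- after }
    else { m$utr5 <- after; m$utr3 <- before }
    models[[length(models) + 1]] <- m
  }
  genes <- gene_models(models)
  n_genes <- length(models)

  # start/stop codons written into the genome, strand-aware
  put <- function(genome, ch, pos1, s) {        # pos1 1-based
    substr(genome[[ch]], pos1, pos1 + nchar(s) - 1) <- s
    genome
  }
  for (m in models) {
    cds_len <- sum(m$cds[, 2] - m$cds[, 1])
    p_start <- genomic_pos_of_cds(m, 1)
    p_stop <- genomic_pos_of_cds(m, cds_len - 2)
    if (m$strand == "+") {
      genome <- put(genome, m$chrom, p_start, "ATG")
      genome <- put(genome, m$chrom, p_stop, "TAA")
    } else {
      genome <- put(genome, m$chrom, p_start - 2, "CAT")  # revcomp(ATG)
      genome <- put(genome, m$chrom, p_stop - 2, "TTA")   # revcomp(TAA)
    }
  }

  # planted gene classes (disjoint)
  planted <- with_seed(child_seed(cfg$seed, "plant"), {
    pool <- sample.int(n_genes)
    need <- cfg$n_fixed_genes + cfg$n_high_pi_genes +
      cfg$n_private_high + cfg$n_private_moderate
    if (need > n_genes) stop("more planted genes requested than genes exist")
    fixed <- pool[seq_len(cfg$n_fixed_genes)]
    hp <- pool[cfg$n_fixed_genes + seq_len(cfg$n_high_pi_genes)]
    pe <- pool[cfg$n_fixed_genes + cfg$n_high_pi_genes +
                 seq_len(cfg$n_private_high + cfg$n_private_moderate)]
    list(fixed = sort(fixed), high_pi = sort(hp),
         effect = pe,
         effect_kind = rep(c("stop_gained", "missense_variant"),
                           c(cfg$n_private_high, cfg$n_private_moderate)))
  })

  # engineer private-effect codons into the genome and define the variants
  eff_list <- list()
  with_seed(child_seed(cfg$seed, "effects"), {
    for (k in seq_along(planted$effect)) {
      m <- models[[planted$effect[k]]]
      kind <- planted$effect_kind[k]
      codon_i <- 12 + k %% 5                     # interior codon, clear of start
      if (kind == "stop_gained") {               # TAC -> TAA at codon pos 3
        ref_codon <- "TAC"; cds_off <- 3 * codon_i; alt_coding <- "A"
      } else {                                   # GAA -> GTA (Glu -> Val)
        ref_codon <- "GAA"; cds_off <- 3 * codon_i - 1; alt_coding <- "T"
      }
      p_first <- genomic_pos_of_cds(m, 3 * codon_i - 2)
      codon_genomic <- if (m$strand == "+") ref_codon else revcomp(ref_codon)
      codon_left <- if (m$strand == "+") p_first else p_first - 2
      genome <- put(genome, m$chrom, codon_left, codon_genomic)
      vpos <- genomic_pos_of_cds(m, cds_off)
      ref_b <- substr(genome[[m$chrom]], vpos, vpos)
      alt_b <- if (m$strand == "+") alt_coding else revcomp(alt_coding)
      eff_list[[k]] <- data.frame(
        chrom = m$chrom, pos = vpos, ref = ref_b, alt = alt_b,
        gene_id = m$gene_id, effect = kind,
        impact = impact_of(kind), stringsAsFactors = FALSE)
    }
  })
  planted_eff <- if (length(eff_list)) do.call(rbind, eff_list) else NULL

  # site positions per chromosome
  site_tbl <- with_seed(child_seed(cfg$seed, "sites"), {
    per_chrom <- round(cfg$n_sites / cfg$n_chrom)
    out <- list()
    gene_iv <- genes$index
    for (ch in chroms) {
      pos <- sort(sample.int(cfg$chrom_len, per_chrom))
      if (cfg$genic_thinning < 1) {
        gi <- gene_iv[gene_iv$chrom == ch, , drop = FALSE]
        genic <- rep(FALSE, length(pos))
        for (r in seq_len(nrow(gi)))
          genic <- genic | (pos > gi$start[r] & pos <= gi$end[r])
        keep <- !genic | stats::runif(length(pos)) < cfg$genic_thinning
        pos <- pos[keep]
      }
      out[[ch]] <- pos
    }
    # guaranteed sites inside planted fixed / high-pi genes
    cls <- rep("neutral", n_genes)
    cls[planted$fixed] <- "fixed_difference"
    cls[planted$high_pi] <- "high_pi"
    extra <- list()
    for (gidx in c(planted$fixed, planted$high_pi)) {
      m <- models[[gidx]]
      p <- m$start + round((m$end - m$start) *
                             seq_len(cfg$sites_per_planted_gene) /
                             (cfg$sites_per_planted_gene + 1))
      extra[[length(extra) + 1]] <- data.frame(chrom = m$chrom, pos = p,
                                               class = cls[gidx],
                                               gene_idx = gidx,
                                               stringsAsFactors = FALSE)
    }
    extra <- if (length(extra)) do.call(rbind, extra) else
      data.frame(chrom = character(0), pos = integer(0),
                 class = character(0), gene_idx = integer(0))
    tabs <- lapply(chroms, function(ch) {
      p <- out[[ch]]
      ex <- extra[extra$chrom == ch, , drop = FALSE]
      drop <- p %in% c(ex$pos, planted_eff$pos[planted_eff$chrom == ch])
      p <- p[!drop]
      d <- data.frame(chrom = ch, pos = p, class = "neutral",
                      gene_idx = NA_integer_, stringsAsFactors = FALSE)
      pe <- if (is.null(planted_eff)) NULL else
        planted_eff[planted_eff$chrom == ch, , drop = FALSE]
      if (!is.null(pe) && nrow(pe))
        d <- rbind(d, data.frame(chrom = ch, pos = pe$pos, class = "effect",
                                 gene_idx = NA_integer_,
                                 stringsAsFactors = FALSE))
      d <- rbind(d, ex[, c("chrom", "pos", "class", "gene_idx")])
      d <- d[!duplicated(d$pos), , drop = FALSE]
      d[order(d$pos), , drop = FALSE]
    })
    do.call(rbind, tabs)
  })
  # every site inside a planted gene span carries the planted pattern
  for (gidx in planted$fixed) {
    m <- models[[gidx]]
    inside <- site_tbl$chrom == m$chrom & site_tbl$pos > m$start &
      site_tbl$pos <= m$end
    site_tbl$class[inside] <- "fixed_difference"
  }
  for (gidx in planted$high_pi) {
    m <- models[[gidx]]
    inside <- site_tbl$chrom == m$chrom & site_tbl$pos > m$start &
      site_tbl$pos <= m$end & site_tbl$class != "effect"
    site_tbl$class[inside] <- "high_pi"
  }
  S <- nrow(site_tbl)
  ordinary <- which(site_tbl$class == "neutral")

  # tri-allelic and high-missingness markings among ordinary sites
  marks <- with_seed(child_seed(cfg$seed, "marks"), {
    need <- cfg$n_triallelic + cfg$n_high_missing
    if (need > length(ordinary)) stop("not enough ordinary sites to mark")
    pick <- sample(ordinary, need)
    k_miss_samples <- floor(0.30 * n_samp) + 1L
    list(triallelic = sort(pick[seq_len(cfg$n_triallelic)]),
         high_missing = sort(pick[cfg$n_triallelic + seq_len(cfg$n_high_missing)]),
         miss_who = lapply(seq_len(cfg$n_high_missing), function(i)
           sample.int(n_samp, k_miss_samples)))
  })

  # allele frequencies: ancestral -> subspecies -> accession
  subs <- c("pepo", "ovifera")
  freqs <- with_seed(child_seed(cfg$seed, "freqs"), {
    # frequencies are drawn per founder segment, not per site: two
    # indicator variables with unequal p cannot be fully correlated, so
    # sites sharing a backbone must share a frequency for the copying model
    # to yield high short-range r2. Segments span geometrically many LD
    # blocks (frequency redrawn at block borders with prob freq_turnover),
    # giving a two-scale decay: backbone switches within segments,
    # frequency turnover across them — and segments, not sites, are the
    # statistically independent units of the genome.
    bid <- (site_tbl$pos - 1) %/% cfg$block_len
    seg <- integer(S)
    seg_n <- 0L
    for (ch in chroms) {
      on_ch <- which(site_tbl$chrom == ch)
      ub <- sort(unique(bid[on_ch]))
      gaps <- c(1L, diff(ub))
      change <- stats::runif(length(ub)) < 1 - (1 - cfg$freq_turnover)^gaps
      change[1] <- TRUE
      seg_of_block <- seg_n + cumsum(change)
      seg_n <- seg_n + sum(change)
      seg[on_ch] <- seg_of_block[match(bid[on_ch], ub)]
    }
    p_anc_s <- stats::runif(seg_n, cfg$p_anc_range[1], cfg$p_anc_range[2])
    p_sub_s <- vapply(subs, function(s)
      balding_nichols_freqs(p_anc_s, cfg$F_subspecies), numeric(seg_n))
    p_acc_s <- vapply(seq_len(n_samp), function(i)
      balding_nichols_freqs(p_sub_s[, cfg$samples$subspecies[i]],
                            cfg$F_morphotype), numeric(seg_n))
    list(p_anc = p_anc_s[seg],
         p_sub = p_sub_s[seg, , drop = FALSE],
         p_acc = p_acc_s[seg, , drop = FALSE])
  })
  # planted overrides
  is_fixed_site <- site_tbl$class == "fixed_difference"
  is_hp_site <- site_tbl$class == "high_pi"
  for (i in seq_len(n_samp)) {
    ss <- cfg$samples$subspecies[i]
    freqs$p_acc[is_fixed_site, i] <- if (ss == "pepo") 1 else 0
    freqs$p_acc[is_hp_site, i] <- if (ss == cfg$high_pi_group) 0.5 else 0
  }
  freqs$p_sub[is_fixed_site, "pepo"] <- 1
  freqs$p_sub[is_fixed_site, "ovifera"] <- 0
  freqs$p_sub[is_hp_site, ] <- 0
  freqs$p_sub[is_hp_site, cfg$high_pi_group] <- 0.5

  # haplotypes -> pooled accession calls
  gt_a <- matrix(NA_integer_, n_samp, S)
  gt_b <- matrix(NA_integer_, n_samp, S)
  pool_f <- matrix(NA_real_, n_samp, S)
  with_seed(child_seed(cfg$seed, "geno"), {
    for (ch in chroms) {
      sel <- which(site_tbl$chrom == ch)
      pos <- site_tbl$pos[sel]
      for (i in seq_len(n_samp)) {
        H <- simulate_haplotypes(2L * cfg$samples$pool_size[i], pos,
                                 freqs$p_acc[sel, i],
                                 cfg$block_len, cfg$recomb_between_blocks)
        f <- colMeans(H)
        cl <- pool_calls(f, cfg$pool_het_min)
        gt_a[i, sel] <- cl$a
        gt_b[i, sel] <- cl$b
        pool_f[i, sel] <- f
      }
    }
  })

  # depth, quality, missingness
  dp <- gq <- NULL
  with_seed(child_seed(cfg$seed, "depth"), {
    dp <- matrix(pmax(cfg$depth_floor,
                      stats::rnbinom(n_samp * S, mu = cfg$depth_mean,
                                     size = cfg$depth_size)),
                 n_samp, S)
    gq <- matrix(pmin(99, pmax(cfg$gq_floor,
                               round(stats::rnorm(n_samp * S, cfg$gq_mean,
                                                  cfg$gq_sd)))),
                 n_samp, S)
    if (cfg$missing_rate > 0) {
      mis <- matrix(stats::runif(n_samp * S) < cfg$missing_rate, n_samp, S)
      gt_a[mis] <- NA; gt_b[mis] <- NA
      dp[mis] <- 0L; gq[mis] <- 0L
    }
  })

  # alleles: ref from genome, alt random different base
  base_at <- function(ch, p) substr(genome[[ch]], p, p)
  refs <- vapply(seq_len(S), function(i)
    base_at(site_tbl$chrom[i], site_tbl$pos[i]), character(1))
  ts_partner <- c(A = "G", G = "A", C = "T", T = "C")
  alts <- with_seed(child_seed(cfg$seed, "alleles"), {
    vapply(refs, function(r) {
      if (stats::runif(1) < cfg$ts_prob) return(unname(ts_partner[r]))
      sample(setdiff(c("A", "C", "G", "T"), c(r, ts_partner[r])), 1)
    }, character(1), USE.NAMES = FALSE)
  })
  # planted effect variants keep their engineered alleles
  eff_sites <- integer(0)
  if (!is.null(planted_eff)) {
    key <- paste(site_tbl$chrom, site_tbl$pos)
    eff_sites <- match(paste(planted_eff$chrom, planted_eff$pos), key)
    alts[eff_sites] <- planted_eff$alt
    stopifnot(all(refs[eff_sites] == planted_eff$ref))
    carriers <- which(cfg$samples[[cfg$private_group_by]] == cfg$private_group)
    for (j in seq_along(eff_sites)) {
      s <- eff_sites[j]
      gt_a[, s] <- 0L; gt_b[, s] <- 0L
      gt_a[carriers, s] <- 0L; gt_b[carriers, s] <- 1L
      dp[, s] <- max(cfg$depth_mean, 10)
      gq[, s] <- max(cfg$gq_mean, 20)
    }
  }
  # tri-allelic sites: add a second alternate carried by two accessions
  alt2 <- with_seed(child_seed(cfg$seed, "triallelic"), {
    vapply(marks$triallelic, function(s) {
      taken <- c(refs[s], alts[s])
      sample(setdiff(c("A", "C", "G", "T"), taken), 1)
    }, character(1))
  })
  alt_str <- alts
  for (j in seq_along(marks$triallelic)) {
    s <- marks$triallelic[j]
    alt_str[s] <- paste(alts[s], alt2[j], sep = ",")
    who <- ((j - 1) %% n_samp) + 1L
    gt_a[who, s] <- 0L; gt_b[who, s] <- 2L
    dp[, s] <- max(cfg$depth_mean, 10); gq[, s] <- max(cfg$gq_mean, 20)
  }
  # high-missingness sites: depth below the mask threshold for >30% of calls
  for (j in seq_along(marks$high_missing)) {
    s <- marks$high_missing[j]
    dp[marks$miss_who[[j]], s] <- 5L
    dp[-marks$miss_who[[j]], s] <- pmax(dp[-marks$miss_who[[j]], s], 10L)
    gq[, s] <- pmax(gq[, s], 20L)
  }

  sites <- data.frame(chrom = site_tbl$chrom, pos = site_tbl$pos,
                      ref = refs, alt = alt_str, stringsAsFactors = FALSE)
  coh <- cohort(sites, gt_a, gt_b, dp = dp, gq = gq, samples = cfg$samples)

  ref <- structure(genome, lengths = stats::setNames(nchar(genome), chroms),
                   class = "ref_genome")

  cls <- rep("neutral", n_genes)
  cls[planted$fixed] <- "fixed_difference"
  cls[planted$high_pi] <- "high_pi"
  cls[planted$effect] <- "private_effect"
  truth <- list(
    seed = cfg$seed,
    F_subspecies = cfg$F_subspecies,
    F_morphotype = cfg$F_morphotype,
    site_class = site_tbl$class,
    p_anc = freqs$p_anc, p_sub = freqs$p_sub, p_acc = freqs$p_acc,
    pool_f = pool_f,
    gene_class = data.frame(gene_id = genes$index$gene_id, class = cls,
                            stringsAsFactors = FALSE),
    planted_effects = planted_eff,
    planted_effect_group = cfg$private_group,
    planted_triallelic = data.frame(
      chrom = site_tbl$chrom[marks$triallelic],
      pos = site_tbl$pos[marks$triallelic], stringsAsFactors = FALSE),
    planted_high_missing = data.frame(
      chrom = site_tbl$chrom[marks$high_missing],
      pos = site_tbl$pos[marks$high_missing], stringsAsFactors = FALSE),
    het_fraction = stats::setNames(
      rowMeans(!is.na(coh$gt_a) & coh$gt_a != coh$gt_b),
      cfg$samples$accession)
  )
  list(cohort = coh, genes = genes, ref = ref, meta = cfg$samples,
       truth = truth, config = cfg)
}

# 1-based genomic position of a coding-strand CDS offset (1-based).
genomic_pos_of_cds <- function(gene, cds_pos) {
  cds <- gene$cds
  lens <- cds[, 2] - cds[, 1]
  if (gene$strand == "+") {
    off <- cds_pos
    for (k in seq_len(nrow(cds))) {
      if (off <= lens[k]) return(cds[k, 1] + off)    # 0-based + off = 1-based
      off <- off - lens[k]
    }
  } else {
    off <- cds_pos
    for (k in rev(seq_len(nrow(cds)))) {
      if (off <= lens[k]) return(cds[k, 2] - off + 1)
    off <- off - lens[k]
    }
  }
  stop("CDS offset out of range")
}

#' Write a simulated cohort bundle to files
#'
#' Emits `ref.fa`, `genes.gff3`, `cohort.vcf`, `meta.tsv` and `truth.json`
#' under `dir`, then self-checks: the VCF re-read through [read_vcf()] must
#' reproduce the emitted genotypes exactly.
#'
#' @param config a [sim_config()]
#' @param dir output directory (created if needed)
#' @return the [simulate_cohort()] bundle with `$paths` added, invisibly
#' @export
emit_cohort <- function(config, dir) {
  sim <- simulate_cohort(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    fasta = file.path(dir, "ref.fa"), gff3 = file.path(dir, "genes.gff3"),
    vcf = file.path(dir, "cohort.vcf"), meta = file.path(dir, "meta.tsv"),
    truth = file.path(dir, "truth.json")
  )
  seqs <- Biostrings::DNAStringSet(unclass(sim$ref))
  Biostrings::writeXStringSet(seqs, paths$fasta, width = 80)
  write_gff3(sim$genes, paths$gff3)
  write_vcf(sim$cohort, paths$vcf, contig_lengths = chrom_lengths(sim$ref))
  utils::write.table(sim$meta, paths$meta, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_json <- sim$truth
  truth_json$p_sub <- NULL; truth_json$p_acc <- NULL; truth_json$pool_f <- NULL
  truth_json$p_anc <- NULL; truth_json$site_class <- NULL
  jsonlite::write_json(truth_json, paths$truth, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")

  back <- suppressWarnings(read_vcf(paths$vcf, sim$meta))
  ok <- identical(back$gt_a, sim$cohort$gt_a) &&
    identical(back$gt_b, sim$cohort$gt_b)
  if (!ok) stop("self-check failed: emitted VCF does not reproduce truth genotypes")
  sim$paths <- paths
  invisible(sim)
}

# Minimal GFF3 writer for the generator's gene models.
write_gff3 <- function(genes, path) {
  ln <- c("##gff-version 3")
  for (m in genes$models) {
    s1 <- m$start + 1                            # back to 1-based inclusive
    attr_g <- sprintf("ID=%s", m$gene_id)
    attr_m <- sprintf("ID=%s;Parent=%s", m$transcript_id, m$gene_id)
    ln <- c(ln,
            paste(m$chrom, "popgenscan", "gene", s1, m$end, ".", m$strand, ".",
                  attr_g, sep = "\t"),
            paste(m$chrom, "popgenscan", "mRNA", s1, m$end, ".", m$strand, ".",
                  attr_m, sep = "\t"))
    for (k in seq_len(nrow(m$exons)))
      ln <- c(ln, paste(m$chrom, "popgenscan", "exon",
                        m$exons[k, 1] + 1, m$exons[k, 2], ".", m$strand, ".",
                        sprintf("ID=%s.e%d;Parent=%s", m$transcript_id, k,
                                m$transcript_id), sep = "\t"))
    if (m$coding) for (k in seq_len(nrow(m$cds)))
      ln <- c(ln, paste(m$chrom, "popgenscan", "CDS",
                        m$cds[k, 1] + 1, m$cds[k, 2], ".", m$strand, "0",
                        sprintf("ID=%s.c%d;Parent=%s", m$transcript_id, k,
                                m$transcript_id), sep = "\t"))
  }
  writeLines(ln, path)
  invisible(path)
}
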