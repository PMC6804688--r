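#' Read a multi-sample VCF into a cohort
#'
#' Parses GT and, when present, per-genotype DP and GQ. Records are sorted by
#' (chrom, pos) on read; multi-allelic records are retained (they are removed
#' later by [filter_sites()]). Phase separators (`|`) are accepted but phase
#' is ignored: the pipeline is phase-free.
#'
#' @param path VCF file (plain or gzipped)
#' @param meta sample metadata data.frame (`accession`, `morphotype`,
#'   `subspecies`, optional `pool_size`); every accession must be a sample
#'   column of the VCF. Defaults to a minimal table built from the VCF's
#'   sample names.
#' @return a [cohort()]
#' @export
read_vcf <- function(path, meta = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  vcf_samples <- colnames(v@gt)[-1]
  if (is.null(meta)) {
    meta <- data.frame(accession = vcf_samples, morphotype = NA_character_,
                       subspecies = NA_character_, stringsAsFactors = FALSE)
  }
  missing_s <- setdiff(meta$accession, vcf_samples)
  if (length(missing_s))
    stop("sample(s) in metadata absent from VCF: ",
         paste(missing_s, collapse = ", "))

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[, meta$accession, drop = FALSE]
  fmt <- v@gt[, "FORMAT"]
  has_dp <- all(grepl("(^|:)DP(:|$)", fmt))
  has_gq <- all(grepl("(^|:)GQ(:|$)", fmt))
  get_num <- function(el) {
    m <- suppressWarnings(vcfR::extract.gt(v, element = el, as.numeric = TRUE))
    m <- m[, meta$accession, drop = FALSE]
    m[is.na(m)] <- 0
    t(m)
  }
  n_site <- nrow(fix)
  n_samp <- nrow(meta)
  dp <- if (has_dp) get_num("DP") else NULL
  gq <- if (has_gq) get_num("GQ") else NULL
  if (!has_dp) warning("VCF lacks per-genotype DP; depth mask will be disabled")
  if (!has_gq) warning("VCF lacks per-genotype GQ; quality mask will be disabled")

  # split "a/b" (or "a|b") into two allele-index matrices
  gt <- t(gt)                                   # samples x sites
  a1 <- sub("[/|].*$", "", gt)
  a2 <- sub("^.*[/|]", "", gt)
  to_idx <- function(m) {
    m[m == "." | is.na(m)] <- NA
    storage.mode(m) <- "integer"
    m
  }
  gt_a <- to_idx(a1); gt_b <- to_idx(a2)
  half <- xor(is.na(gt_a), is.na(gt_b))
  if (any(half)) { gt_a[half] <- NA; gt_b[half] <- NA }

  sites <- data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = toupper(fix[, "REF"]), alt = toupper(fix[, "ALT"]),
    stringsAsFactors = FALSE
  )
  cohort(sites, gt_a, gt_b, dp = dp, gq = gq, samples = meta)
}

#' Write a cohort to a VCF 4.2 file
#'
#' Emits GT:DP:GQ genotype fields. Round-trips bit-exactly with [read_vcf()]
#' for biallelic SNPs.
#'
#' @param x a [cohort()]
#' @param path output file
#' @param contig_lengths optional named vector of chromosome lengths for the
#'   header `##contig` lines
#' @return `path`, invisibly
#' @export
write_vcf <- function(x, path, contig_lengths = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=popgenscan",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">'
  )
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", x$samples$accession),
                      collapse = "\t"))
  a <- ifelse(is.na(x$gt_a), ".", x$gt_a)
  b <- ifelse(is.na(x$gt_b), ".", x$gt_b)
  calls <- matrix(sprintf("%s/%s:%d:%d", a, b,
                          as.integer(x$dp), as.integer(x$gq)),
                  nrow = nrow(a))
  body <- paste(
    x$sites$chrom, x$sites$pos, ".", x$sites$ref, x$sites$alt, ".", "PASS",
    ".", "GT:DP:GQ",
    apply(calls, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' One gene model per mRNA; genes with several mRNAs are collapsed to the
#' isoform with the longest total CDS (with a warning), matching per-gene
#' statistics that assume a single transcript. UTRs are derived as exon
#' minus CDS, partitioned 5'/3' by strand. Intervals are stored 0-based
#' half-open internally; the GFF3 1-based inclusive convention is converted
#' at this boundary only.
#'
#' @param path GFF3 file
#' @return a `gene_models` object: list of per-gene records plus an index
#'   data.frame (`$index`: gene_id, chrom, start, end, strand, coding)
#' @export
read_gff3 <- function(path) {
  g <- as.data.frame(rtracklayer::readGFF(path))
  g$ID <- as.character(g$ID)
  g$Parent <- vapply(g$Parent, function(p)
    if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  feats <- tolower(g$type)
  mrna <- g[feats %in% c("mrna", "transcript"), , drop = FALSE]
  genes_df <- g[feats == "gene", , drop = FALSE]
  sub_feats <- g[feats %in% c("exon", "cds"), , drop = FALSE]
  if (any(feats == "cds")) {
    orphan <- g[feats == "cds" & !(g$Parent %in% mrna$ID), , drop = FALSE]
    if (nrow(orphan)) stop("CDS feature without parent mRNA in ", path)
  }

  build_one <- function(mr) {
    kids <- sub_feats[sub_feats$Parent == mr$ID, , drop = FALSE]
    ex <- kids[tolower(kids$type) == "exon", , drop = FALSE]
    cds <- kids[tolower(kids$type) == "cds", , drop = FALSE]
    to0 <- function(d) {
      if (!nrow(d)) return(matrix(numeric(0), ncol = 2))
      m <- cbind(d$start - 1L, d$end)     # 1-based inclusive -> 0-based half-open
      m[order(m[, 1]), , drop = FALSE]
    }
    exons <- to0(ex); cdsm <- to0(cds)
    if (nrow(exons) > 1 && any(exons[-1, 1] < exons[-nrow(exons), 2]))
      stop("overlapping exons in mRNA ", mr$ID)
    coding <- nrow(cdsm) > 0
    if (coding) {
      cds_len <- sum(cdsm[, 2] - cdsm[, 1])
      if (cds_len %% 3 != 0)
        warning("CDS length of ", mr$ID, " not divisible by 3")
    }
    utr <- interval_diff(exons, cdsm)
    strand <- as.character(mr$strand)
    if (coding) {
      cds_lo <- min(cdsm[, 1]); cds_hi <- max(cdsm[, 2])
      before <- utr[utr[, 2] <= cds_lo, , drop = FALSE]
      after <- utr[utr[, 1] >= cds_hi, , drop = FALSE]
      if (strand == "+") { utr5 <- before; utr3 <- after }
      else { utr5 <- after; utr3 <- before }
    } else {
      utr5 <- utr3 <- matrix(numeric(0), ncol = 2)
    }
    gene_id <- if (!is.na(mr$Parent)) mr$Parent else mr$ID
    list(gene_id = gene_id, transcript_id = mr$ID,
         chrom = as.character(mr$seqid), strand = strand,
         start = mr$start - 1L, end = mr$end,
         exons = exons, cds = cdsm, utr5 = utr5, utr3 = utr3,
         coding = coding)
  }

  models <- lapply(seq_len(nrow(mrna)), function(i) build_one(mrna[i, , drop = FALSE]))
  # collapse multi-mRNA genes to the longest CDS
  gid <- vapply(models, `[[`, character(1), "gene_id")
  if (anyDuplicated(gid)) {
    warning("gene(s) with multiple mRNAs collapsed to longest CDS: ",
            paste(unique(gid[duplicated(gid)]), collapse = ", "))
    cds_len <- vapply(models, function(m)
      if (nrow(m$cds)) sum(m$cds[, 2] - m$cds[, 1]) else 0, numeric(1))
    keep <- unlist(lapply(split(seq_along(models), gid), function(ix)
      ix[which.max(cds_len[ix])]), use.names = FALSE)
    models <- models[sort(keep)]
  }
  gene_models(models)
}

# Assemble a gene_models object (list of per-gene records + index).
gene_models <- function(models) {
  idx <- data.frame(
    gene_id = vapply(models, `[[`, character(1), "gene_id"),
    chrom = vapply(models, `[[`, character(1), "chrom"),
    start = vapply(models, function(m) as.numeric(m$start), numeric(1)),
    end = vapply(models, function(m) as.numeric(m$end), numeric(1)),
    strand = vapply(models, `[[`, character(1), "strand"),
    coding = vapply(models, `[[`, logical(1), "coding"),
    stringsAsFactors = FALSE
  )
  structure(list(models = models, index = idx), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes (%d coding) on %d sequence(s)\n",
              nrow(x$index), sum(x$index$coding),
              length(unique(x$index$chrom))))
  invisible(x)
}

# Set difference of 0-based half-open interval sets (both sorted matrices).
interval_diff <- function(a, b) {
  if (!nrow(a)) return(a)
  if (!nrow(b)) return(a)
  out <- list()
  for (i in seq_len(nrow(a))) {
    segs <- matrix(a[i, ], ncol = 2)
    for (j in seq_len(nrow(b))) {
      nxt <- list()
      for (k in seq_len(nrow(segs))) {
        s <- segs[k, 1]; e <- segs[k, 2]
        bs <- b[j, 1]; be <- b[j, 2]
        if (be <= s || bs >= e) { nxt[[length(nxt) + 1]] <- c(s, e); next }
        if (bs > s) nxt[[length(nxt) + 1]] <- c(s, bs)
        if (be < e) nxt[[length(nxt) + 1]] <- c(be, e)
      }
      segs <- if (length(nxt)) do.call(rbind, nxt) else matrix(numeric(0), ncol = 2)
      if (!nrow(segs)) break
    }
    if (nrow(segs)) out[[length(out) + 1]] <- segs
  }
  if (!length(out)) return(matrix(numeric(0), ncol = 2))
  m <- do.call(rbind, out)
  m[order(m[, 1]), , drop = FALSE]
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file
#' @return named character vector of upper-cased sequences, class
#'   `ref_genome`, with a `lengths` attribute
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate sequence id in ", path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  structure(seqs, lengths = stats::setNames(nchar(seqs), ids),
            class = "ref_genome")
}

#' Chromosome lengths of a reference genome
#' @param ref a [read_fasta()] object
#' @return named integer vector
#' @export
chrom_lengths <- function(ref) attr(ref, "lengths")

#' Fetch a reference subsequence
#'
#' @param ref a `ref_genome`
#' @param chrom sequence id
#' @param start,end 1-based inclusive coordinates
#' @return character string
#' @export
fetch_seq <- function(ref, chrom, start, end) {
  if (!chrom %in% names(ref)) stop("unknown sequence: ", chrom)
  len <- nchar(ref[[chrom]])
  if (start < 1 || end > len || start > end)
    stop(sprintf("out-of-range fetch %s:%d-%d (length %d)", chrom, start, end, len))
  substr(ref[[chrom]], start, end)
}

#' Reverse-complement a DNA string
#' @param x character string over ACGT
#' @return reverse complement
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Export a distance matrix as a NEXUS DISTANCES block
#'
#' Writes the square-matrix (`triangle=both`, `labels=left`) DISTANCES block
#' that SplitsTree consumes for Neighbor-net construction. Labels containing
#' whitespace are quoted.
#'
#' @param dm a distance object from [distance_matrix()], or a square symmetric
#'   numeric matrix with dimnames
#' @param path output file
#' @return `path`, invisibly
#' @export
write_distance_nexus <- function(dm, path) {
  m <- as_dist_matrix(dm)
  labels <- rownames(m)
  if (max(abs(m - t(m))) > 1e-9) stop("distance matrix asymmetric beyond 1e-9")
  q <- ifelse(grepl("\\s", labels), sprintf("'%s'", labels), labels)
  rows <- vapply(seq_along(labels), function(i)
    paste(q[i], paste(sprintf("%.10g", m[i, ]), collapse = " ")), character(1))
  writeLines(c(
    "#NEXUS", "",
    "BEGIN Taxa;",
    sprintf("DIMENSIONS ntax=%d;", length(labels)),
    "TAXLABELS",
    paste0("  ", q),
    ";", "END;", "",
    "BEGIN Distances;",
    sprintf("DIMENSIONS ntax=%d;", length(labels)),
    "FORMAT labels=left diagonal triangle=both;",
    "MATRIX",
    paste0("  ", rows),
    ";", "END;"
  ), path)
  invisible(path)
}

#' Read back a NEXUS DISTANCES block written by [write_distance_nexus()]
#' @param path NEXUS file
#' @return square numeric matrix with dimnames
#' @export
read_distance_nexus <- function(path) {
  ln <- readLines(path)
  i0 <- grep("^MATRIX$", ln)
  if (!length(i0)) stop("no MATRIX line found in ", path)
  i1 <- i0[length(i0)]
  rows <- list(); labels <- character(0)
  for (i in seq(i1 + 1, length(ln))) {
    l <- trimws(ln[i])
    if (l == ";") break
    if (startsWith(l, "'")) {
      lab <- sub("^'([^']*)'.*$", "\\1", l)
      rest <- trimws(sub("^'[^']*'", "", l))
    } else {
      lab <- sub("\\s.*$", "", l)
      rest <- trimws(sub("^\\S+", "", l))
    }
    labels <- c(labels, lab)
    rows[[length(rows) + 1]] <- as.numeric(strsplit(rest, "\\s+")[[1]])
  }
  m <- do.call(rbind, rows)
  dimnames(m) <- list(labels, labels)
  m
}

#' Export a distance matrix in PHYLIP square format
#' @inheritParams write_distance_nexus
#' @return `path`, invisibly
#' @export
write_distance_phylip <- function(dm, path) {
  m <- as_dist_matrix(dm)
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(format(rownames(m)[i], width = 10),
          paste(sprintf("%.10g", m[i, ]), collapse = " ")), character(1))
  writeLines(c(sprintf("%5d", nrow(m)), rows), path)
  invisible(path)
}

as_dist_matrix <- function(dm) {
  if (inherits(dm, "kosman_dist")) {
    m <- dm$d
    dimnames(m) <- list(dm$labels, dm$labels)
    return(m)
  }
  if (!is.matrix(dm) || nrow(dm) != ncol(dm) || is.null(rownames(dm)))
    stop("need a square labelled matrix or a kosman_dist object")
  dm
}

#' Write a window-statistic track as TSV
#'
#' Columns `chrom,start,end,stat,value,n_sites`; intervals are BED-style
#' 0-based half-open; `NaN`/`NA` values are serialized as `NA`. These plain
#' tracks replace Circos rendering.
#'
#' @param stats a window-stat data.frame as produced by the windowed
#'   statistics (`chrom`, `start`, `end`, `stat`, `value`, `n_sites`)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_track_table <- function(stats, path) {
  cols <- c("chrom", "start", "end", "stat", "value", "n_sites")
  if (!nrow(stats)) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  stopifnot(all(cols %in% names(stats)))
  utils::write.table(stats[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a track table written by [write_track_table()]
#' @param path TSV file
#' @return data.frame
#' @export
read_track_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", na.strings = "NA",
                    stringsAsFactors = FALSE)
}
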