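#' Per-site Weir-Cockerham Fst variance components
#'
#' The two-population moment estimator: per biallelic SNP the among-
#' population (`a`), among-individual-within-population (`b`) and
#' within-individual (`c`) variance components, and theta = a / (a + b + c).
#' A site is usable when each group has at least one called diploid and the
#' mean group size exceeds one. Sites monomorphic across both groups have
#' all components zero and undefined theta (`NaN`). Reported theta is
#' clamped to [-1, 1]; negative estimates are kept (flooring would bias the
#' ratio-of-sums aggregation upward).
#'
#' @param x a filtered [cohort()]
#' @param group1,group2 disjoint accession-name vectors (e.g. the two
#'   subspecies)
#' @param snps_only restrict to SNP sites; other sites get `NA` rows
#' @return data.frame, one row per site: `n1`, `n2`, `p1`, `p2`, `h1`, `h2`,
#'   `n_bar`, `n_c`, `p_bar`, `s2`, `h_bar`, `a`, `b`, `c`, `theta`
#' @export
wc_fst_site <- function(x, group1, group2, snps_only = TRUE) {
  if (!length(group1) || !length(group2)) stop("both groups must be non-empty")
  if (length(intersect(group1, group2)))
    stop("groups overlap: ", paste(intersect(group1, group2), collapse = ", "))
  stats1 <- group_site_stats(x, group1)
  stats2 <- group_site_stats(x, group2)
  n1 <- stats1$n; n2 <- stats2$n
  p1 <- stats1$p; p2 <- stats2$p
  h1 <- stats1$h; h2 <- stats2$h
  r <- 2
  n_bar <- (n1 + n2) / r
  usable <- n1 >= 1 & n2 >= 1 & n_bar > 1
  n_c <- ((r * n_bar) - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- (n1 * h1 + n2 * h2) / (r * n_bar)

  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) *
       (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 - h_bar / 4))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - ((r - 1) / r) * s2 -
       ((2 * n_bar - 1) / (4 * n_bar)) * h_bar)
  cc <- h_bar / 2

  mono <- p_bar %in% c(0, 1) & h_bar == 0
  a[mono] <- 0; b[mono] <- 0; cc[mono] <- 0
  bad <- !usable
  if (snps_only) bad <- bad | !x$sites$is_snp
  for (v in c("a", "b", "cc", "n_c", "s2"))
    assign(v, replace(get(v), bad, NA_real_))
  denom <- a + b + cc
  theta <- ifelse(!is.na(denom) & denom != 0, a / denom, NaN)
  theta <- pmin(pmax(theta, -1), 1)
  data.frame(n1 = n1, n2 = n2, p1 = p1, p2 = p2, h1 = h1, h2 = h2,
             n_bar = n_bar, n_c = n_c, p_bar = p_bar, s2 = s2, h_bar = h_bar,
             a = a, b = b, c = cc, theta = theta)
}

# Per-site called-diploid count, alt-allele frequency and observed-het
# frequency within a sample group.
group_site_stats <- function(x, group) {
  si <- resolve_samples(x, group)
  ga <- x$gt_a[si, , drop = FALSE] > 0
  gb <- x$gt_b[si, , drop = FALSE] > 0
  n <- colSums(!is.na(ga))
  alt <- colSums(ga, na.rm = TRUE) + colSums(gb, na.rm = TRUE)
  het <- colSums(ga != gb, na.rm = TRUE)
  list(n = n, p = ifelse(n > 0, alt / (2 * n), NaN),
       h = ifelse(n > 0, het / n, NaN))
}

#' Multi-site Weir-Cockerham theta over intervals
#'
#' Ratio-of-sums combination (the estimator's recommended multi-locus form):
#' per interval, theta = sum(a) / sum(a + b + c) over usable sites. `NaN`
#' when an interval has no usable polymorphic site. Also reports whether
#' theta equals 1 in the structural sense `|sum(b + c)| < 1e-12` with
#' positive among-population variance — the class of fully fixed intervals.
#'
#' @param components output of [wc_fst_site()]
#' @param sites the site table the components refer to (`x$sites`)
#' @param intervals data.frame `chrom`, `start`, `end` (0-based half-open),
#'   plus any id columns, e.g. windows or gene spans
#' @return `intervals` with `theta`, `sum_a`, `sum_bc`, `n_usable`,
#'   `is_fixed` appended
#' @export
fst_aggregate <- function(components, sites, intervals) {
  stopifnot(nrow(components) == nrow(sites))
  usable <- !is.na(components$a) & (components$a + components$b + components$c) != 0
  res <- intervals
  res$theta <- NaN
  res$sum_a <- NA_real_; res$sum_bc <- NA_real_
  res$n_usable <- 0L; res$is_fixed <- FALSE
  for (i in seq_len(nrow(intervals))) {
    sel <- which(sites$chrom == intervals$chrom[i] &
                   sites$pos > intervals$start[i] &
                   sites$pos <= intervals$end[i] & usable)
    res$n_usable[i] <- length(sel)
    if (!length(sel)) next
    sa <- sum(components$a[sel])
    sbc <- sum(components$b[sel] + components$c[sel])
    res$sum_a[i] <- sa; res$sum_bc[i] <- sbc
    if (sa + sbc != 0) res$theta[i] <- min(max(sa / (sa + sbc), -1), 1)
    res$is_fixed[i] <- abs(sbc) < 1e-12 && sa > 0
  }
  res
}

#' Constants of Tajima's D
#'
#' The standard sample-size constants a1, a2, b1, b2, c1, c2, e1, e2 for
#' `n` sequences.
#'
#' @param n number of sequences (>= 2)
#' @return named list of constants
#' @export
tajima_constants <- function(n) {
  if (n < 2) stop("need n >= 2 sequences")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D over an interval within a group
#'
#' Complete-case estimator: only sites called in every group member are
#' used, keeping the sequence count `n = 2 x diploids` constant as the
#' constants require. `D = (pi_sum - S / a1) / sqrt(e1 S + e2 S (S - 1))`,
#' `NaN` when the interval holds no segregating site or `n < 4`.
#'
#' @param x a filtered [cohort()]
#' @param group accession names
#' @param interval list or one-row data.frame with `chrom`, `start`, `end`
#'   (0-based half-open); `NULL` for all sites
#' @param snps_only restrict to SNP sites
#' @return list: `n`, `S`, `pi_sum`, `D`, plus the constants
#' @export
tajima_d <- function(x, group, interval = NULL, snps_only = TRUE) {
  si <- resolve_samples(x, group)
  sel <- rep(TRUE, n_sites(x))
  if (snps_only) sel <- sel & x$sites$is_snp
  if (!is.null(interval))
    sel <- sel & x$sites$chrom == interval$chrom &
      x$sites$pos > interval$start & x$sites$pos <= interval$end
  ga <- x$gt_a[si, sel, drop = FALSE] > 0
  gb <- x$gt_b[si, sel, drop = FALSE] > 0
  complete <- colSums(is.na(ga)) == 0
  ga <- ga[, complete, drop = FALSE]; gb <- gb[, complete, drop = FALSE]
  n <- 2L * length(si)
  if (n < 4) {
    warning("Tajima's D undefined for n < 4 sequences")
    return(list(n = n, S = NA_integer_, pi_sum = NA_real_, D = NaN))
  }
  c_alt <- colSums(ga) + colSums(gb)
  seg <- c_alt > 0 & c_alt < n
  S <- sum(seg)
  k <- tajima_constants(n)
  if (S == 0)
    return(c(list(n = n, S = 0L, pi_sum = 0, D = NaN), k))
  ca <- c_alt[seg]
  pi_sum <- sum(2 * ca * (n - ca) / (n * (n - 1)))
  D <- (pi_sum - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  c(list(n = n, S = as.integer(S), pi_sum = pi_sum, D = D), k)
}

#' Tajima's D from derived-allele counts
#'
#' Computes the statistic directly from a vector of per-site derived allele
#' counts out of `n` sequences — the natural interface for coalescent
#' samples from [hudson_coalescent()].
#'
#' @param n number of sequences
#' @param counts derived allele count per segregating site (values in 1..n-1)
#' @return Tajima's D (`NaN` when no segregating sites)
#' @export
tajima_d_from_counts <- function(n, counts) {
  counts <- counts[counts > 0 & counts < n]
  S <- length(counts)
  if (S == 0) return(NaN)
  k <- tajima_constants(n)
  pi_sum <- sum(2 * counts * (n - counts) / (n * (n - 1)))
  (pi_sum - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

#' Per-gene diversity, Tajima's D and Fst
#'
#' Assembles the gene-level scan table: per gene, per-subspecies per-bp
#' diversity (site-pi summed over the gene, divided by the gene span or the
#' exonic length), per-subspecies Tajima's D, and the multi-site
#' Weir-Cockerham theta over the gene's sites. Genes spanning no SNP get
#' zero pi and `NaN` D and theta.
#'
#' @param x a filtered [cohort()]
#' @param genes a `gene_models` object
#' @param groups named list of two accession-name vectors, e.g.
#'   `list(pepo = ..., ovifera = ...)`
#' @param pi_denominator `"span"` (gene length, default) or `"exonic"`
#' @return data.frame: `gene_id`, `chrom`, `start`, `end`, `n_sites`,
#'   `pi_<group>`, `tajima_d_<group>`, `fst`, `fst_is_fixed`
#' @export
gene_stats <- function(x, genes, groups, pi_denominator = c("span", "exonic")) {
  pi_denominator <- match.arg(pi_denominator)
  stopifnot(length(groups) == 2, !is.null(names(groups)))
  idx <- genes$index
  comp <- wc_fst_site(x, groups[[1]], groups[[2]])
  agg <- fst_aggregate(comp, x$sites,
                       idx[, c("chrom", "start", "end"), drop = FALSE])
  pis <- lapply(groups, function(g) site_pi(x, g))
  exon_len <- vapply(genes$models, function(m)
    if (nrow(m$exons)) sum(m$exons[, 2] - m$exons[, 1]) else 0, numeric(1))

  out <- data.frame(gene_id = idx$gene_id, chrom = idx$chrom,
                    start = idx$start, end = idx$end,
                    n_sites = 0L, stringsAsFactors = FALSE)
  for (gname in names(groups)) {
    out[[paste0("pi_", gname)]] <- NA_real_
    out[[paste0("tajima_d_", gname)]] <- NaN
  }
  for (i in seq_len(nrow(idx))) {
    sel <- which(x$sites$chrom == idx$chrom[i] & x$sites$is_snp &
                   x$sites$pos > idx$start[i] & x$sites$pos <= idx$end[i])
    out$n_sites[i] <- length(sel)
    len <- if (pi_denominator == "span") idx$end[i] - idx$start[i] else exon_len[i]
    iv <- list(chrom = idx$chrom[i], start = idx$start[i], end = idx$end[i])
    for (gname in names(groups)) {
      v <- pis[[gname]][sel]
      out[[paste0("pi_", gname)]][i] <-
        if (len > 0) sum(v[!is.nan(v)], na.rm = TRUE) / len else NaN
      if (length(sel))
        out[[paste0("tajima_d_", gname)]][i] <-
          suppressWarnings(tajima_d(x, groups[[gname]], iv)$D)
    }
  }
  out$fst <- agg$theta
  out$fst_is_fixed <- agg$is_fixed
  out
}

#' Candidate-gene Fst scan
#'
#' Lists genes whose between-group theta exceeds each threshold (strictly)
#' and genes with theta equal to 1.00 in the structural sense
#' `|sum(b + c)| < 1e-12` (the class of genes fully fixed between groups),
#' with counts and percentages over scanned genes (genes with a defined
#' theta).
#'
#' @param stats output of [gene_stats()]
#' @param thresholds strict lower bounds to report (default 0.80)
#' @return list: `n_scanned`, per-threshold `list(genes, n, pct)` under
#'   `above`, and `fixed = list(genes, n, pct)` for theta = 1.00
#' @export
candidate_fst_scan <- function(stats, thresholds = 0.80) {
  scanned <- stats[!is.nan(stats$fst), , drop = FALSE]
  n <- nrow(scanned)
  above <- lapply(thresholds, function(t) {
    g <- scanned$gene_id[scanned$fst > t]
    list(threshold = t, genes = g, n = length(g),
         pct = if (n > 0) 100 * length(g) / n else NaN)
  })
  names(above) <- sprintf("fst_gt_%.2f", thresholds)
  fx <- scanned$gene_id[scanned$fst_is_fixed]
  list(n_scanned = n, above = above,
       fixed = list(genes = fx, n = length(fx),
                    pct = if (n > 0) 100 * length(fx) / n else NaN))
}

#' Subspecies-exclusive high-diversity genes
#'
#' Flags, per group, genes with per-bp diversity strictly above the 99th
#' percentile (by default) of that group's gene-diversity distribution, and
#' returns the genes flagged in exactly one group.
#'
#' @param stats output of [gene_stats()]
#' @param percentile quantile probability (default 0.99)
#' @return list with per-group `flagged`, per-group `exclusive`, and the
#'   thresholds used
#' @export
high_diversity_scan <- function(stats, percentile = 0.99) {
  pi_cols <- grep("^pi_", names(stats), value = TRUE)
  groups <- sub("^pi_", "", pi_cols)
  flagged <- lapply(pi_cols, function(cl) {
    v <- stats[[cl]]
    q <- stats::quantile(v[!is.na(v)], percentile, names = FALSE)
    stats$gene_id[!is.na(v) & v > q]
  })
  names(flagged) <- groups
  exclusive <- lapply(seq_along(groups), function(i)
    setdiff(flagged[[i]], unlist(flagged[-i])))
  names(exclusive) <- groups
  thresholds <- vapply(pi_cols, function(cl)
    stats::quantile(stats[[cl]][!is.na(stats[[cl]])], percentile,
                    names = FALSE), numeric(1))
  names(thresholds) <- groups
  list(flagged = flagged, exclusive = exclusive, percentile = percentile,
       thresholds = thresholds)
}
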