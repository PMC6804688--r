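#' Pairwise linkage disequilibrium r-squared
#'
#' For every same-chromosome pair of retained biallelic SNPs within
#' `max_dist` bp, the squared Pearson correlation of alternate-allele
#' dosages (0/1/2) over pairwise-complete samples — the phase-free composite
#' (Rogers-Huff style) estimator. Pairs where either site is monomorphic
#' among the jointly called samples, or with fewer than `min_n` complete
#' samples, are skipped.
#'
#' @param x a filtered [cohort()]
#' @param group accession names (default: all)
#' @param max_dist maximum pair distance in bp (default 0.5 Mb)
#' @param min_n minimum samples called at both sites (default 3)
#' @param min_maf optional minor-allele-frequency floor applied per site
#'   before pairing (default 0: no pruning)
#' @param max_sites_per_chrom optional cap; when a chromosome holds more
#'   SNPs, an evenly spaced deterministic subset is used (keeps dense
#'   cohorts at desk scale without randomness)
#' @return data.frame: `chrom`, `pos_a`, `pos_b`, `distance`, `r2`, `n_used`
#' @export
pairwise_r2 <- function(x, group = NULL, max_dist = 500000, min_n = 3,
                        min_maf = 0, max_sites_per_chrom = Inf) {
  si <- resolve_samples(x, group)
  snp <- which(x$sites$is_snp)
  dos <- dosage(x)[si, , drop = FALSE]
  if (min_maf > 0) {
    p <- colMeans(dos, na.rm = TRUE) / 2
    maf <- pmin(p, 1 - p)
    snp <- snp[!is.na(maf[snp]) & maf[snp] >= min_maf]
  }
  out <- list()
  for (ch in unique(x$sites$chrom[snp])) {
    idx <- snp[x$sites$chrom[snp] == ch]
    if (length(idx) > max_sites_per_chrom)
      idx <- idx[unique(round(seq(1, length(idx),
                                  length.out = max_sites_per_chrom)))]
    pos <- x$sites$pos[idx]
    m <- length(idx)
    if (m < 2) next
    D <- dos[, idx, drop = FALSE]
    for (i in seq_len(m - 1)) {
      jmax <- findInterval(pos[i] + max_dist, pos)
      if (jmax <= i) next
      jr <- (i + 1):jmax
      xi <- D[, i]
      r <- suppressWarnings(
        stats::cor(xi, D[, jr, drop = FALSE], use = "pairwise.complete.obs"))
      nu <- colSums(!is.na(xi) & !is.na(D[, jr, drop = FALSE]))
      ok <- !is.na(r[1, ]) & nu >= min_n
      if (!any(ok)) next
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, pos_a = pos[i], pos_b = pos[jr][ok],
        distance = pos[jr][ok] - pos[i],
        r2 = as.numeric(r[1, ok])^2, n_used = nu[ok],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), pos_a = integer(0),
                      pos_b = integer(0), distance = integer(0),
                      r2 = numeric(0), n_used = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Local-polynomial fit of LD decay
#'
#' Tricube-weighted local quadratic regression (loess, degree 2) of pair
#' r-squared on distance, evaluated on a regular grid, with the smallest
#' grid distance at which the fitted curve first drops below each requested
#' threshold.
#'
#' @param pairs output of [pairwise_r2()]
#' @param span loess span (fraction of pairs in each local window)
#' @param grid_step evaluation grid step in bp
#' @param thresholds r-squared levels whose first crossing distance is
#'   reported (`NA` when the fitted curve never drops below a level)
#' @param max_pairs cap on pairs entering the fit; beyond it an evenly
#'   spaced deterministic subset (over the distance-sorted pairs) is used
#' @return list: `grid` (data.frame distance, r2_fit), `crossings` (named
#'   numeric), `span`, `n_pairs_used`
#' @export
ld_decay_fit <- function(pairs, span = 0.3, grid_step = 1000,
                         thresholds = c(0.6, 0.4, 0.3), max_pairs = 100000) {
  if (nrow(pairs) < 50) stop("need at least 50 pairs to fit LD decay")
  pairs <- pairs[order(pairs$distance), , drop = FALSE]
  if (nrow(pairs) > max_pairs)
    pairs <- pairs[unique(round(seq(1, nrow(pairs), length.out = max_pairs))), ]
  fit <- stats::loess(r2 ~ distance, data = pairs, span = span, degree = 2,
                      family = "gaussian")
  grid <- seq(0, max(pairs$distance), by = grid_step)
  pred <- stats::predict(fit, newdata = data.frame(distance = grid))
  # constant extrapolation outside the observed distance range
  inside <- which(!is.na(pred))
  if (length(inside) && inside[1] > 1)
    pred[seq_len(inside[1] - 1)] <- pred[inside[1]]
  if (length(inside) && inside[length(inside)] < length(pred))
    pred[(inside[length(inside)] + 1):length(pred)] <- pred[inside[length(inside)]]
  pred <- pmin(pmax(pred, 0), 1)                 # fitted curve on the r2 scale
  crossings <- vapply(thresholds, function(t) {
    i <- which(pred < t)[1]
    if (is.na(i)) NA_real_ else grid[i]
  }, numeric(1))
  names(crossings) <- sprintf("r2_below_%g", thresholds)
  list(grid = data.frame(distance = grid, r2_fit = as.numeric(pred)),
       crossings = crossings, span = span, n_pairs_used = nrow(pairs))
}

#' Mean LD in genomic windows
#'
#' Mean pair r-squared per window; a pair belongs to the window containing
#' its midpoint. Windows without pairs get `NaN`.
#'
#' @param pairs output of [pairwise_r2()]
#' @param chrom_lengths named vector of chromosome lengths
#' @param window window size in bp (default 50 kb, the LD track window)
#' @return track data.frame (stat `ld_mean`)
#' @export
window_ld <- function(pairs, chrom_lengths, window = 50000) {
  out <- lapply(names(chrom_lengths), function(ch) {
    w <- tile_windows(chrom_lengths[[ch]], window)
    p <- pairs[pairs$chrom == ch, , drop = FALSE]
    val <- rep(NaN, nrow(w)); nn <- rep(0L, nrow(w))
    if (nrow(p)) {
      mid <- (p$pos_a + p$pos_b) / 2
      wi <- window_index(mid, window) + 1L
      m <- rowsum(p$r2, wi) / as.numeric(table(wi))
      val[as.integer(rownames(m))] <- m[, 1]
      cnt <- table(wi)
      nn[as.integer(names(cnt))] <- as.integer(cnt)
    }
    data.frame(chrom = ch, start = w$start, end = w$end, stat = "ld_mean",
               value = val, n_sites = nn, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Bootstrap background LD
#'
#' Estimates the r-squared level expected between unlinked loci at this
#' sample size. Per replication, `n_snps` SNPs are drawn uniformly without
#' replacement genome-wide and r-squared is computed for pairs residing on
#' different chromosomes (capped at `pair_cap` randomly chosen pairs); the
#' replicate mean is recorded. The background-LD value (BLD) is the upper
#' bound of the central 95% interval — the 97.5th percentile — of the
#' replicate means (`mode = "replicate_means"`, default) or of the pooled
#' pair r-squared values (`mode = "pooled"`).
#'
#' @param x a filtered [cohort()]
#' @param group accession names (default: all)
#' @param n_reps replications (default 1000)
#' @param n_snps SNPs drawn per replication (default 1000; when fewer SNPs
#'   exist all are used, with a warning)
#' @param seed integer seed; the computation is bit-reproducible given the
#'   seed and does not disturb the global RNG
#' @param pair_cap maximum inter-chromosomal pairs scored per replication
#' @param mode `"replicate_means"` or `"pooled"`
#' @return list: `bld`, `replicate_means`, `n_snps_per_rep`, `n_reps`,
#'   `pair_cap`, `mode`, `seed`
#' @export
background_ld <- function(x, group = NULL, n_reps = 1000, n_snps = 1000,
                          seed = 1, pair_cap = 50000,
                          mode = c("replicate_means", "pooled")) {
  mode <- match.arg(mode)
  si <- resolve_samples(x, group)
  snp <- which(x$sites$is_snp)
  chrom <- x$sites$chrom[snp]
  if (length(unique(chrom)) < 2)
    stop("background LD needs >= 2 chromosomes (unlinked pairs); ",
         "for single-chromosome data compute distant-window r2 instead")
  D <- dosage(x)[si, snp, drop = FALSE]
  m <- length(snp)
  k <- min(n_snps, m)
  if (k < n_snps)
    warning(sprintf("only %d SNPs available; using all per replication", m))
  means <- numeric(n_reps)
  pooled <- if (mode == "pooled") vector("list", n_reps) else NULL
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      idx <- if (k < m) sample.int(m, k) else seq_len(m)
      ch <- chrom[idx]
      if (k * (k - 1) / 2 <= pair_cap) {
        # few enough SNPs: score every inter-chromosomal pair
        inter <- which(outer(ch, ch, "!=") & upper.tri(matrix(0, k, k)),
                       arr.ind = TRUE)
        ii <- inter[, 1]; jj <- inter[, 2]
      } else {
        # sample the capped pair set directly (uniform over ordered pairs,
        # restricted to different chromosomes)
        ii <- sample.int(k, pair_cap, replace = TRUE)
        jj <- sample.int(k, pair_cap, replace = TRUE)
        keep <- ch[ii] != ch[jj]
        ii <- ii[keep]; jj <- jj[keep]
      }
      r2 <- pair_r2_values(D, idx[ii], idx[jj])
      means[r] <- mean(r2, na.rm = TRUE)
      if (mode == "pooled") pooled[[r]] <- r2[!is.na(r2)]
    }
  })
  valid <- is.finite(means)
  if (!any(valid))
    stop("no replicate produced a defined r2 (all sampled pairs monomorphic)")
  if (!all(valid))
    warning(sprintf("%d of %d replicates had no polymorphic pair and were dropped",
                    sum(!valid), n_reps))
  bld <- if (mode == "pooled")
    stats::quantile(unlist(pooled), 0.975, names = FALSE)
  else
    stats::quantile(means[valid], 0.975, names = FALSE)
  list(bld = min(bld, 1), replicate_means = means, n_valid_reps = sum(valid),
       n_snps_per_rep = k, n_reps = n_reps, pair_cap = pair_cap, mode = mode,
       seed = seed)
}

# Vectorized pairwise-complete r2 for explicit pair index vectors over the
# columns of dosage matrix D (samples x sites).
pair_r2_values <- function(D, ii, jj) {
  A <- D[, ii, drop = FALSE]; B <- D[, jj, drop = FALSE]
  M <- !is.na(A) & !is.na(B)
  A[!M] <- 0; B[!M] <- 0
  n <- colSums(M)
  sa <- colSums(A); sb <- colSums(B)
  saa <- colSums(A * A); sbb <- colSums(B * B); sab <- colSums(A * B)
  cov <- sab - sa * sb / n
  va <- saa - sa^2 / n
  vb <- sbb - sb^2 / n
  r2 <- cov^2 / (va * vb)
  r2[n < 2 | va <= 0 | vb <= 0] <- NA_real_
  pmin(r2, 1)
}
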