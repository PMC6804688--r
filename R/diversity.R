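#' Per-site nucleotide diversity
#'
#' Unbiased pairwise-difference probability at each site within a sample
#' group. With `n` called alleles (2 per called diploid) of which `c` are
#' alternate, `pi = 2 c (n - c) / (n (n - 1))` — the probability that two
#' alleles drawn without replacement differ. Sites with fewer than 4 called
#' alleles give `NaN`.
#'
#' @param x a filtered [cohort()]
#' @param group accession names (default: all samples)
#' @param snps_only restrict to SNP sites (the analysis set); non-SNP sites
#'   receive `NA` so indices stay aligned with `x$sites`
#' @return numeric vector, one value per site of `x`
#' @export
site_pi <- function(x, group = NULL, snps_only = TRUE) {
  si <- resolve_samples(x, group)
  if (!length(si)) stop("empty sample group")
  a <- x$gt_a[si, , drop = FALSE] > 0
  b <- x$gt_b[si, , drop = FALSE] > 0
  n <- 2 * colSums(!is.na(a))
  c_alt <- colSums(a, na.rm = TRUE) + colSums(b, na.rm = TRUE)
  pi <- ifelse(n >= 4, 2 * c_alt * (n - c_alt) / (n * pmax(n - 1, 1)), NaN)
  if (snps_only) pi[!x$sites$is_snp] <- NA
  pi
}

#' Windowed nucleotide diversity
#'
#' Per-bp diversity per non-overlapping window: the sum of per-site pi over
#' the window divided by the full window length in bp (monomorphic positions
#' contribute zero implicitly; a truncated terminal window uses its actual
#' span). Windows with no retained polymorphic site get value 0.
#'
#' @inheritParams site_pi
#' @param chrom_lengths named vector of chromosome lengths
#' @param window window size in bp (1 kb for the diversity boxplots, 100 kb
#'   for genome tracks)
#' @return track data.frame (stat `pi`)
#' @export
window_pi <- function(x, chrom_lengths, group = NULL, window = 100000) {
  pi <- site_pi(x, group)
  out <- lapply(names(chrom_lengths), function(ch) {
    w <- tile_windows(chrom_lengths[[ch]], window)
    on_ch <- which(x$sites$chrom == ch & !is.na(pi) & !is.nan(pi))
    wi <- window_index(x$sites$pos[on_ch], window) + 1L
    s <- rep(0, nrow(w)); nn <- rep(0L, nrow(w))
    if (length(on_ch)) {
      agg <- rowsum(pi[on_ch], wi)
      s[as.integer(rownames(agg))] <- agg[, 1]
      cnt <- table(wi)
      nn[as.integer(names(cnt))] <- as.integer(cnt)
    }
    data.frame(chrom = ch, start = w$start, end = w$end, stat = "pi",
               value = s / (w$end - w$start), n_sites = nn,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Windowed heterozygosity and homozygous-alternate frequency tracks
#'
#' For a group of accessions, per 100 kb window: the fraction of called
#' genotypes that are heterozygous (`het_freq`) and homozygous for a
#' non-reference allele (`homalt_freq`).
#'
#' @inheritParams window_pi
#' @return track data.frame with stats `het_freq` and `homalt_freq`
#' @export
observed_heterozygosity <- function(x, chrom_lengths, group = NULL,
                                    window = 100000) {
  si <- resolve_samples(x, group)
  ga <- x$gt_a[si, , drop = FALSE]
  gb <- x$gt_b[si, , drop = FALSE]
  het <- colSums(!is.na(ga) & ga != gb)
  homalt <- colSums(!is.na(ga) & ga == gb & ga > 0L)
  called <- colSums(!is.na(ga))
  out <- lapply(names(chrom_lengths), function(ch) {
    w <- tile_windows(chrom_lengths[[ch]], window)
    on_ch <- which(x$sites$chrom == ch)
    wi <- window_index(x$sites$pos[on_ch], window) + 1L
    agg <- function(v) {
      s <- rep(0, nrow(w))
      if (length(on_ch)) {
        a <- rowsum(v[on_ch], wi)
        s[as.integer(rownames(a))] <- a[, 1]
      }
      s
    }
    ncall <- agg(called); nhet <- agg(het); nhom <- agg(homalt)
    nn <- rep(0L, nrow(w))
    if (length(on_ch)) {
      cnt <- table(wi); nn[as.integer(names(cnt))] <- as.integer(cnt)
    }
    rbind(
      data.frame(chrom = ch, start = w$start, end = w$end, stat = "het_freq",
                 value = ifelse(ncall > 0, nhet / ncall, NaN), n_sites = nn,
                 stringsAsFactors = FALSE),
      data.frame(chrom = ch, start = w$start, end = w$end, stat = "homalt_freq",
                 value = ifelse(ncall > 0, nhom / ncall, NaN), n_sites = nn,
                 stringsAsFactors = FALSE)
    )
  })
  do.call(rbind, out)
}
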