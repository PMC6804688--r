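#' Genotype cohort container
#'
#' A `cohort` bundles the filtered (or raw) multi-sample genotype matrix with
#' its site table and sample metadata. It is the central object every
#' statistic in the package consumes. Genotypes are stored unphased as two
#' allele-index matrices (`0` = reference, `1`,`2`,... = alternate alleles,
#' `NA` = missing), with per-call read depth (DP) and genotype quality (GQ)
#' matrices alongside.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based, VCF
#'   convention), `ref`, `alt` (comma-separated for multi-allelic records).
#' @param gt_a,gt_b integer matrices, samples x sites, allele indexes or `NA`.
#' @param dp,gq integer matrices, samples x sites; `NULL` when the VCF lacks
#'   the field (the depth/quality mask is then disabled with a warning).
#' @param samples data.frame with columns `accession`, `morphotype`,
#'   `subspecies` and optionally `pool_size` (defaults to 5, the number of
#'   plants pooled per sequenced accession).
#'
#' @return An object of class `cohort`.
#' @export
cohort <- function(sites, gt_a, gt_b, dp = NULL, gq = NULL, samples) {
  stopifnot(is.data.frame(sites), is.data.frame(samples))
  n_site <- nrow(sites)
  n_samp <- nrow(samples)
  if (!all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
    stop("sites must have chrom, pos, ref, alt columns")
  if (!all(c("accession", "morphotype", "subspecies") %in% names(samples)))
    stop("samples must have accession, morphotype, subspecies columns")
  if (is.null(samples$pool_size)) samples$pool_size <- 5L
  for (m in list(gt_a, gt_b)) {
    if (!is.matrix(m) || nrow(m) != n_samp || ncol(m) != n_site)
      stop("genotype matrices must be samples x sites")
  }
  if (any(sites$pos < 1, na.rm = TRUE)) stop("positions must be >= 1")
  if (any(xor(is.na(gt_a), is.na(gt_b))))
    stop("half-missing genotypes are not allowed: both alleles NA or both set")
  has_dp <- !is.null(dp)
  has_gq <- !is.null(gq)
  if (!has_dp) dp <- matrix(0L, n_samp, n_site)
  if (!has_gq) gq <- matrix(0L, n_samp, n_site)
  for (m in c("gt_a", "gt_b", "dp", "gq")) {
    v <- get(m)
    dimnames(v) <- list(samples$accession, NULL)
    assign(m, v)
  }

  alts <- strsplit(as.character(sites$alt), ",", fixed = TRUE)
  alleles_ok <- function(x) grepl("^[ACGT]+$", x)
  sites$ref <- toupper(as.character(sites$ref))
  if (!all(alleles_ok(sites$ref))) stop("reference alleles must be over {A,C,G,T}")
  sites$is_snp <- nchar(sites$ref) == 1L &
    vapply(alts, function(a) all(nchar(a) == 1L), logical(1))
  sites$is_indel <- !sites$is_snp

  ord <- order(sites$chrom, sites$pos)
  key <- paste(sites$chrom, sites$pos, sites$ref, sites$alt)
  if (anyDuplicated(key)) stop("duplicate (chrom, pos, ref, alt) site")

  obj <- structure(list(
    sites = sites[ord, , drop = FALSE],
    gt_a = gt_a[, ord, drop = FALSE],
    gt_b = gt_b[, ord, drop = FALSE],
    dp = dp[, ord, drop = FALSE],
    gq = gq[, ord, drop = FALSE],
    samples = samples,
    has_dp = has_dp,
    has_gq = has_gq,
    masked = FALSE
  ), class = "cohort")
  rownames(obj$sites) <- NULL
  obj
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d accessions x %d sites (%d SNPs, %d indels)%s\n",
    nrow(x$samples), nrow(x$sites), sum(x$sites$is_snp),
    sum(x$sites$is_indel),
    if (x$masked) ", depth/quality-masked" else ""
  ))
  invisible(x)
}

#' Number of sites / samples in a cohort
#' @param x a [cohort()]
#' @return integer count
#' @export
n_sites <- function(x) nrow(x$sites)

#' @rdname n_sites
#' @export
n_samples <- function(x) nrow(x$samples)

#' Subset a cohort by site index and/or sample
#'
#' @param x a [cohort()]
#' @param sites integer or logical index over sites
#' @param samples accession names, or integer/logical index over samples
#' @return a new `cohort`
#' @export
subset_cohort <- function(x, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(n_sites(x))
  si <- resolve_samples(x, samples)
  out <- x
  out$sites <- x$sites[sites, , drop = FALSE]
  rownames(out$sites) <- NULL
  for (f in c("gt_a", "gt_b", "dp", "gq"))
    out[[f]] <- x[[f]][si, sites, drop = FALSE]
  out$samples <- x$samples[si, , drop = FALSE]
  rownames(out$samples) <- NULL
  out
}

# Resolve a sample spec (names, index, or NULL = all) to integer indices.
resolve_samples <- function(x, samples) {
  if (is.null(samples)) return(seq_len(nrow(x$samples)))
  if (is.character(samples)) {
    i <- match(samples, x$samples$accession)
    if (anyNA(i)) stop("unknown accession(s): ",
                       paste(samples[is.na(i)], collapse = ", "))
    return(i)
  }
  idx <- seq_len(nrow(x$samples))[samples]
  if (anyNA(idx)) stop("sample index out of range")
  idx
}

#' Accessions belonging to a subspecies or morphotype group
#'
#' @param x a [cohort()]
#' @param group value to match (e.g. `"pepo"`)
#' @param by metadata column, `"subspecies"` (default) or `"morphotype"`
#' @return character vector of accession names
#' @export
group_samples <- function(x, group, by = "subspecies") {
  stopifnot(by %in% c("subspecies", "morphotype", "accession"))
  x$samples$accession[x$samples[[by]] == group]
}

#' Alternate-allele dosage matrix
#'
#' Codes each diploid call as the number of non-reference alleles (0, 1, 2);
#' missing calls are `NA`. For multi-allelic sites any alternate allele
#' counts, so dosage is only meaningful after biallelic filtering.
#'
#' @param x a [cohort()]
#' @param samples optional sample subset (names or indices)
#' @return numeric matrix samples x sites
#' @export
dosage <- function(x, samples = NULL) {
  si <- resolve_samples(x, samples)
  (x$gt_a[si, , drop = FALSE] > 0) + (x$gt_b[si, , drop = FALSE] > 0)
}

# 0-based half-open window index for 1-based positions.
window_index <- function(pos, window) (pos - 1L) %/% window

# All windows tiling [0, chrom_len): data.frame(start, end), 0-based half-open.
tile_windows <- function(chrom_len, window) {
  if (window <= 0) stop("window size must be positive")
  starts <- seq.int(0L, max(0L, chrom_len - 1L), by = window)
  data.frame(start = starts, end = pmin(starts + window, chrom_len))
}

# Internal RNG scope: run code with a fixed seed, restoring global state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a root seed and a component label, so adding one
# component never perturbs another's stream. Kept below 2^31.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.numeric(seed) * 7919 + h) %% 2147483647
}
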