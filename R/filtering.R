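#' Genotype- and site-filter configuration
#'
#' Defaults follow the study pipeline: genotypes with a depth lower than 10
#' reads or a quality lower than 20 are set to missing (strict `<`), then
#' non-biallelic variants and variants with more than 30% missing calls
#' (strict `>`) are removed, so exact boundary values survive. Indels are
#' retained through filtering but excluded from the diversity, LD, Fst,
#' Tajima's D and distance statistics when `snps_only_for_stats` is `TRUE`.
#'
#' @param min_depth minimum per-call read depth (reads)
#' @param min_gq minimum per-call genotype quality
#' @param max_missing_frac maximum tolerated per-site missing fraction
#' @param biallelic_only drop sites with more than two alleles
#' @param snps_only_for_stats restrict downstream statistics to SNPs
#' @return a `filter_config` list
#' @export
filter_config <- function(min_depth = 10, min_gq = 20, max_missing_frac = 0.30,
                          biallelic_only = TRUE, snps_only_for_stats = TRUE) {
  stopifnot(min_depth >= 0, min_gq >= 0,
            max_missing_frac >= 0, max_missing_frac <= 1)
  structure(list(min_depth = min_depth, min_gq = min_gq,
                 max_missing_frac = max_missing_frac,
                 biallelic_only = biallelic_only,
                 snps_only_for_stats = snps_only_for_stats),
            class = "filter_config")
}

#' Mask low-confidence genotype calls
#'
#' Sets every call with depth below `min_depth` or quality below `min_gq`
#' (strictly lower) to missing. The input cohort is not modified. When the
#' VCF carried no DP (or GQ) field the corresponding mask is disabled with
#' a warning rather than failing.
#'
#' @param x a [cohort()]
#' @param cfg a [filter_config()]
#' @return a new masked `cohort`
#' @export
mask_genotypes <- function(x, cfg = filter_config()) {
  bad <- matrix(FALSE, n_samples(x), n_sites(x))
  if (x$has_dp) bad <- bad | (x$dp < cfg$min_depth)
  else if (cfg$min_depth > 0) warning("no DP field: depth mask disabled")
  if (x$has_gq) bad <- bad | (x$gq < cfg$min_gq)
  else if (cfg$min_gq > 0) warning("no GQ field: quality mask disabled")
  x$gt_a[bad] <- NA
  x$gt_b[bad] <- NA
  x$masked <- TRUE
  x
}

#' Remove non-biallelic and high-missingness sites
#'
#' Applied after [mask_genotypes()] (enforced). A site is removed when its
#' declared alleles (reference plus alternates) exceed two, or when its
#' missing-call fraction is strictly greater than `max_missing_frac`. Each
#' removed site is attributed to the first rule that removes it
#' (non-biallelic checked first), giving deterministic report accounting:
#' `removed_nonbiallelic + removed_missing + retained = input`.
#'
#' @inheritParams mask_genotypes
#' @return list with `cohort` (filtered) and `report` (counts per rule)
#' @export
filter_sites <- function(x, cfg = filter_config()) {
  if (!x$masked)
    stop("filter_sites expects a depth/quality-masked cohort; run mask_genotypes() first")
  n_alleles <- 1L + vapply(strsplit(x$sites$alt, ",", fixed = TRUE),
                           length, integer(1))
  nonbi <- if (cfg$biallelic_only) n_alleles > 2L else rep(FALSE, n_sites(x))
  miss_frac <- colMeans(is.na(x$gt_a))
  high_miss <- miss_frac > cfg$max_missing_frac & !nonbi
  keep <- !nonbi & !high_miss
  report <- list(
    n_input = n_sites(x),
    removed_nonbiallelic = sum(nonbi),
    removed_missing = sum(high_miss),
    retained = sum(keep)
  )
  list(cohort = subset_cohort(x, sites = keep), report = report)
}

#' Per-accession variant summary
#'
#' For each accession, each called site is classified as invariant
#' (homozygous reference), biallelic-variable (heterozygous: one allele
#' identical to and one different from the reference) or
#' monoallelic-variable (homozygous for a non-reference allele). Percentages
#' of biallelic/monoallelic are over that accession's variable sites; the
#' missing percentage and observed heterozygosity Ho are over all retained
#' sites.
#'
#' @param x a filtered [cohort()]
#' @return data.frame, one row per accession: `accession`, `n_variable`,
#'   `pct_biallelic`, `pct_monoallelic`, `pct_missing`, `ho`
#' @export
accession_summary <- function(x) {
  n_site <- n_sites(x)
  het <- !is.na(x$gt_a) & (x$gt_a != x$gt_b) & (x$gt_a == 0L | x$gt_b == 0L)
  # heterozygous with two different non-reference alleles also counts as
  # variable; after biallelic filtering this cannot occur, but classify as
  # het (one ref-differing allele pair) for robustness
  het_nonref <- !is.na(x$gt_a) & (x$gt_a != x$gt_b) & x$gt_a > 0L & x$gt_b > 0L
  homalt <- !is.na(x$gt_a) & (x$gt_a == x$gt_b) & x$gt_a > 0L
  n_het <- rowSums(het) + rowSums(het_nonref)
  n_hom <- rowSums(homalt)
  n_var <- n_het + n_hom
  n_miss <- rowSums(is.na(x$gt_a))
  data.frame(
    accession = x$samples$accession,
    n_variable = n_var,
    pct_biallelic = ifelse(n_var > 0, 100 * n_het / n_var, NaN),
    pct_monoallelic = ifelse(n_var > 0, 100 * n_hom / n_var, NaN),
    pct_missing = 100 * n_miss / n_site,
    ho = n_het / n_site,
    stringsAsFactors = FALSE
  )
}

#' SNP counts in genomic windows
#'
#' Counts retained SNP sites per non-overlapping window, and summarizes
#' per-chromosome totals and per-kb densities.
#'
#' @param x a filtered [cohort()]
#' @param chrom_lengths named vector of chromosome lengths (bp), e.g. from
#'   [chrom_lengths()]
#' @param window window size in bp (default 100 kb)
#' @return list with `windows` (track data.frame, stat `snp_count`) and
#'   `chromosomes` (chrom, n_snps, length, density_per_kb)
#' @export
snp_density_windows <- function(x, chrom_lengths, window = 100000) {
  if (window <= 0) stop("window size must be positive")
  sites <- x$sites[x$sites$is_snp, , drop = FALSE]
  out <- lapply(names(chrom_lengths), function(ch) {
    w <- tile_windows(chrom_lengths[[ch]], window)
    pos <- sites$pos[sites$chrom == ch]
    cnt <- tabulate(window_index(pos, window) + 1L, nbins = nrow(w))
    data.frame(chrom = ch, start = w$start, end = w$end, stat = "snp_count",
               value = cnt, n_sites = cnt, stringsAsFactors = FALSE)
  })
  windows <- do.call(rbind, out)
  per_chrom <- data.frame(
    chrom = names(chrom_lengths),
    n_snps = vapply(names(chrom_lengths),
                    function(ch) sum(sites$chrom == ch), numeric(1)),
    length = as.numeric(chrom_lengths),
    stringsAsFactors = FALSE
  )
  per_chrom$density_per_kb <- 1000 * per_chrom$n_snps / per_chrom$length
  rownames(per_chrom) <- NULL
  list(windows = windows, chromosomes = per_chrom)
}

#' Per-chromosome homogeneity test of SNP density
#'
#' One-sample one-tailed t test, per chromosome, of the window SNP counts
#' against the genome-wide mean window density, with alternative "chromosome
#' mean greater than genome mean". Chromosomes whose windows all sit at or
#' below the genome mean therefore give p near 1, reproducing the
#' "homogeneous distribution" check.
#'
#' @param windows the `windows` track from [snp_density_windows()]
#' @return data.frame: `chrom`, `t`, `p`
#' @export
density_homogeneity_test <- function(windows) {
  mu <- mean(windows$value)
  res <- lapply(split(windows, windows$chrom), function(d) {
    if (nrow(d) < 2 || stats::sd(d$value) == 0) {
      if (nrow(d) < 2) warning("chromosome ", d$chrom[1], ": <2 windows, NaN")
      tt <- if (nrow(d) >= 2 && mean(d$value) == mu) list(statistic = 0, p.value = 0.5)
            else list(statistic = NaN, p.value = NaN)
    } else {
      t0 <- stats::t.test(d$value, mu = mu, alternative = "greater")
      tt <- list(statistic = unname(t0$statistic), p.value = t0$p.value)
    }
    data.frame(chrom = d$chrom[1], t = tt$statistic, p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Regression of SNP density on gene density
#'
#' Ordinary least squares of per-window SNP count on per-window gene count,
#' quantifying the (weak, negative) association between gene density and
#' SNP accumulation.
#'
#' @param snp_windows `windows` track from [snp_density_windows()]
#' @param gene_windows matching track of per-window gene counts (see
#'   [gene_density_windows()])
#' @return list: `slope`, `r2`, `p` (two-sided, for the slope)
#' @export
gene_snp_density_regression <- function(snp_windows, gene_windows) {
  key <- function(d) paste(d$chrom, d$start)
  m <- match(key(snp_windows), key(gene_windows))
  if (anyNA(m)) stop("window grids do not match")
  y <- snp_windows$value
  xg <- gene_windows$value[m]
  if (length(y) < 3) stop("need at least 3 windows")
  if (stats::sd(xg) == 0) stop("gene density has zero variance")
  fit <- stats::lm(y ~ xg)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       r2 = sm$r.squared,
       p = sm$coefficients[2, 4])
}

#' Gene counts in genomic windows
#'
#' Counts genes per window by gene start position (each gene counted once).
#'
#' @param genes a `gene_models` object
#' @param chrom_lengths named vector of chromosome lengths
#' @param window window size in bp
#' @return a track data.frame (stat `gene_count`)
#' @export
gene_density_windows <- function(genes, chrom_lengths, window = 100000) {
  out <- lapply(names(chrom_lengths), function(ch) {
    w <- tile_windows(chrom_lengths[[ch]], window)
    starts <- genes$index$start[genes$index$chrom == ch]     # 0-based
    cnt <- tabulate(starts %/% window + 1L, nbins = nrow(w))
    data.frame(chrom = ch, start = w$start, end = w$end, stat = "gene_count",
               value = cnt, n_sites = cnt, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
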