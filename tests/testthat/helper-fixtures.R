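# Builders and independent oracles shared across the suite.

# Build a cohort from compact genotype strings ("0/1", "./."), one row per
# sample, one column per site.
make_cohort <- function(gt, chrom = NULL, pos = NULL, ref = NULL, alt = NULL,
                        dp = NULL, gq = NULL, samples = NULL, masked = FALSE) {
  gt <- as.matrix(gt)
  ns <- nrow(gt); nv <- ncol(gt)
  if (is.null(chrom)) chrom <- rep("chr1", nv)
  if (is.null(pos)) pos <- seq_len(nv) * 100L
  if (is.null(ref)) ref <- rep("A", nv)
  if (is.null(alt)) alt <- rep("T", nv)
  if (is.null(dp)) dp <- matrix(30L, ns, nv)
  if (is.null(gq)) gq <- matrix(99L, ns, nv)
  if (is.null(samples))
    samples <- data.frame(
      accession = paste0("s", seq_len(ns)),
      morphotype = paste0("m", seq_len(ns)),
      subspecies = rep(c("pepo", "ovifera"), length.out = ns),
      stringsAsFactors = FALSE)
  a <- sub("[/|].*$", "", gt); b <- sub("^.*[/|]", "", gt)
  to_i <- function(m) { m[m == "."] <- NA; storage.mode(m) <- "integer"; m }
  x <- cohort(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                         stringsAsFactors = FALSE),
              to_i(a), to_i(b), dp = dp, gq = gq, samples = samples)
  x$masked <- masked
  x
}

# Two-group cohort with explicit per-group genotype strings.
make_two_group_cohort <- function(gt_pepo, gt_ovifera, ...) {
  gt <- rbind(as.matrix(gt_pepo), as.matrix(gt_ovifera))
  n1 <- nrow(as.matrix(gt_pepo)); n2 <- nrow(as.matrix(gt_ovifera))
  samples <- data.frame(
    accession = c(paste0("p", seq_len(n1)), paste0("o", seq_len(n2))),
    morphotype = c(paste0("p", seq_len(n1)), paste0("o", seq_len(n2))),
    subspecies = c(rep("pepo", n1), rep("ovifera", n2)),
    stringsAsFactors = FALSE)
  make_cohort(gt, samples = samples, ...)
}

# ---- independent oracles ---------------------------------------------------

# Per-site pi by explicit enumeration of all allele pairs.
pi_pair_enumeration <- function(alleles) {
  n <- length(alleles)
  if (n < 4) return(NaN)
  diff <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    diff <- diff + (alleles[i] != alleles[j])
  diff / choose(n, 2)
}

# Weir-Cockerham two-population theta written directly from the published
# variance-component algebra (scalar, loop-free of the package kernel).
wc_theta_oracle <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  ssq <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (ssq - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * ssq - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * ssq -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# Kosman-Leonard locus similarity by explicit multiset intersection.
kl_similarity_oracle <- function(g1, g2) {
  t1 <- table(g1); t2 <- table(g2)
  shared <- intersect(names(t1), names(t2))
  sum(pmin(t1[shared], t2[shared])) / 2
}

kl_distance_oracle <- function(a1, b1, a2, b2) {
  used <- !is.na(a1) & !is.na(a2)
  s <- mapply(function(w, x, y, z) kl_similarity_oracle(c(w, x), c(y, z)),
              a1[used], b1[used], a2[used], b2[used])
  1 - mean(s)
}

# Tajima's D transcribed independently from the standard constants.
tajima_d_oracle <- function(n, counts) {
  counts <- counts[counts > 0 & counts < n]
  S <- length(counts)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  pi_sum <- sum(2 * counts * (n - counts)) / (n * (n - 1))
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Direct Balding-Nichols two-population diploid genotype cohort (binomial
# sampling, no pooling, no LD) for estimator-recovery checks.
bn_two_pop_cohort <- function(n_per_pop, n_sites, F, seed,
                              p_range = c(0.05, 0.95)) {
  set.seed(seed)
  p_anc <- runif(n_sites, p_range[1], p_range[2])
  draw <- function(p) {
    pp <- balding_nichols_freqs(p, F)
    g <- matrix(rbinom(2L * n_per_pop * n_sites, 1,
                       rep(pp, each = 2L * n_per_pop)),
                nrow = 2L * n_per_pop)
    list(a = g[seq_len(n_per_pop) * 2L - 1L, , drop = FALSE],
         b = g[seq_len(n_per_pop) * 2L, , drop = FALSE])
  }
  g1 <- draw(p_anc); g2 <- draw(p_anc)
  samples <- data.frame(
    accession = c(paste0("p", seq_len(n_per_pop)),
                  paste0("o", seq_len(n_per_pop))),
    morphotype = NA_character_,
    subspecies = rep(c("pepo", "ovifera"), each = n_per_pop),
    stringsAsFactors = FALSE)
  x <- cohort(data.frame(chrom = "chr1", pos = seq_len(n_sites) * 10L,
                         ref = "A", alt = "T", stringsAsFactors = FALSE),
              rbind(g1$a, g2$a), rbind(g1$b, g2$b), samples = samples)
  x$masked <- TRUE
  x
}
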