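test_that("pairwise r2 matches dosage-correlation examples and range limit", {
  # identical dosage columns -> r2 = 1
  x <- make_cohort(rbind(c("0/0", "0/0"), c("0/1", "0/1"),
                         c("1/1", "1/1"), c("0/1", "0/1")),
                   pos = c(100L, 200L))
  p <- pairwise_r2(x)
  expect_equal(p$r2, 1)
  expect_equal(p$n_used, 4L)
  # orthogonal dosages (0,0,2,2) vs (0,2,0,2) -> r2 = 0
  y <- make_cohort(rbind(c("0/0", "0/0"), c("0/0", "1/1"),
                         c("1/1", "0/0"), c("1/1", "1/1")),
                   pos = c(100L, 200L))
  expect_equal(pairwise_r2(y)$r2, 0)
  # pairs beyond max_dist absent
  z <- make_cohort(rbind(c("0/1", "0/1"), c("0/0", "0/1"),
                         c("1/1", "0/0"), c("0/1", "1/1")),
                   pos = c(100L, 600100L))
  expect_equal(nrow(pairwise_r2(z)), 0L)
  expect_equal(nrow(pairwise_r2(z, max_dist = 700000)), 1L)
  # monomorphic site among used samples skipped
  m <- make_cohort(rbind(c("0/0", "0/1"), c("0/0", "0/1"),
                         c("0/0", "1/1"), c("0/0", "0/0")),
                   pos = c(100L, 200L))
  expect_equal(nrow(pairwise_r2(m)), 0L)
})

test_that("composite dosage r2 approximates gametic r2 under HWE", {
  # random mating from known haplotype frequencies; gametic r2 = D^2/(p1q1p2q2)
  set.seed(11)
  hap_freq <- c(ab = 0.5, aB = 0.1, Ab = 0.1, AB = 0.3)  # D = 0.1
  D <- hap_freq["AB"] - (hap_freq["AB"] + hap_freq["Ab"]) *
    (hap_freq["AB"] + hap_freq["aB"])
  pA <- hap_freq["AB"] + hap_freq["Ab"]
  pB <- hap_freq["AB"] + hap_freq["aB"]
  r2_gametic <- as.numeric(D^2 / (pA * (1 - pA) * pB * (1 - pB)))
  n <- 500
  hap <- sample(names(hap_freq), 2 * n, TRUE, prob = hap_freq)
  A <- matrix(as.integer(substr(hap, 1, 1) == "A"), n, 2)
  B <- matrix(as.integer(substr(hap, 2, 2) == "B"), n, 2)
  gt <- cbind(paste(A[, 1], A[, 2], sep = "/"),
              paste(B[, 1], B[, 2], sep = "/"))
  x <- make_cohort(gt, pos = c(100L, 200L))
  expect_lt(abs(pairwise_r2(x)$r2 - r2_gametic), 0.05)
})

test_that("LD decay fit is exact on constant data and finds no crossing", {
  set.seed(3)
  pairs <- data.frame(chrom = "c1", pos_a = 1L, pos_b = 1L,
                      distance = sort(sample(1000:400000, 500)),
                      r2 = 0.5, n_used = 8L)
  f <- ld_decay_fit(pairs)
  expect_equal(f$grid$r2_fit, rep(0.5, nrow(f$grid)), tolerance = 1e-8)
  expect_true(is.na(f$crossings["r2_below_0.4"]))
  expect_false(is.na(f$crossings["r2_below_0.6"]))
  expect_error(ld_decay_fit(pairs[1:10, ]), "50 pairs")
})

test_that("LD decay fit recovers a planted exponential curve within 0.05", {
  set.seed(4)
  d <- sort(sample(1000:500000, 4000, replace = TRUE))
  pairs <- data.frame(chrom = "c1", pos_a = 1L, pos_b = 1L, distance = d,
                      r2 = pmin(1, pmax(0, exp(-d / 1e5) +
                                          rnorm(length(d), 0, 0.01))),
                      n_used = 8L)
  f <- ld_decay_fit(pairs)
  sel <- f$grid$distance >= 10000 & f$grid$distance <= 400000
  expect_lt(max(abs(f$grid$r2_fit[sel] - exp(-f$grid$distance[sel] / 1e5))),
            0.05)
  # crossing of 0.4 near the analytic 91.6 kb
  expect_lt(abs(f$crossings[["r2_below_0.4"]] - 1e5 * log(1 / 0.4)), 10000)
})

test_that("windowed LD assigns pairs by midpoint and averages r2", {
  pairs <- data.frame(chrom = "c1",
                      pos_a = c(1000L, 60000L, 62000L),
                      pos_b = c(9000L, 70000L, 74000L),
                      distance = c(8000L, 10000L, 12000L),
                      r2 = c(0.7, 0.2, 0.4), n_used = 8L)
  w <- window_ld(pairs, c(c1 = 100000L), window = 50000)
  expect_equal(w$value[1], 0.7)                  # single pair
  expect_equal(w$value[2], 0.3)                  # mean of 0.2, 0.4
  none <- window_ld(pairs[0, ], c(c1 = 100000L), window = 50000)
  expect_true(all(is.nan(none$value)))
})

test_that("background LD is degenerate-correct, reproducible and warns", {
  # duplicated genotype columns across two chromosomes -> every pair r2 = 1
  gt <- matrix(rep(c("0/0", "0/1", "1/1", "0/1", "0/0", "1/1", "0/1", "0/0"),
                   10), 8, 10)
  x <- make_cohort(gt, chrom = rep(c("chr1", "chr2"), each = 5),
                   pos = rep(seq_len(5) * 100L, 2))
  b <- background_ld(x, n_reps = 20, n_snps = 10, seed = 9)
  expect_equal(b$bld, 1)
  expect_warning(background_ld(x, n_reps = 2, n_snps = 50, seed = 9),
                 "using all")
  # bit-reproducible under a fixed seed, without touching the global RNG
  set.seed(123); before <- runif(1)
  b1 <- background_ld(x, n_reps = 20, n_snps = 10, seed = 9)
  set.seed(123); expect_equal(runif(1), before)
  expect_identical(b1$replicate_means, b$replicate_means)
  # single chromosome rejected
  x1 <- make_cohort(gt, chrom = rep("chr1", 10), pos = seq_len(10) * 100L)
  expect_error(background_ld(x1, seed = 1), "2 chromosomes")
})

test_that("background LD depends on chromosome labels only through identity", {
  # renaming chromosomes (site order unchanged) leaves the bootstrap
  # bit-identical: labels enter only through the unlinked-pair test
  set.seed(5)
  gt <- matrix(sample(c("0/0", "0/1", "1/1"), 8 * 40, TRUE), 8, 40)
  chrom <- rep(c("chr1", "chr2", "chr3", "chr4"), each = 10)
  pos <- rep(seq_len(10) * 100L, 4)
  x <- make_cohort(gt, chrom = chrom, pos = pos)
  relab <- c(chr1 = "a_one", chr2 = "b_two", chr3 = "c_three", chr4 = "d_four")
  y <- make_cohort(gt, chrom = unname(relab[chrom]), pos = pos)
  bx <- background_ld(x, n_reps = 30, n_snps = 20, seed = 2)
  by <- background_ld(y, n_reps = 30, n_snps = 20, seed = 2)
  expect_identical(bx$replicate_means, by$replicate_means)
  expect_equal(bx$bld, by$bld)
})

test_that("mean replicate r2 for independent loci tracks the 1/n expectation", {
  set.seed(6)
  n_samp <- 30
  gt <- matrix(paste(rbinom(n_samp * 60, 1, 0.5),
                     rbinom(n_samp * 60, 1, 0.5), sep = "/"),
               n_samp, 60)
  samples <- data.frame(accession = paste0("s", seq_len(n_samp)),
                        morphotype = NA, subspecies = "pepo")
  x <- make_cohort(gt, chrom = rep(c("chr1", "chr2"), each = 30),
                   pos = rep(seq_len(30) * 100L, 2), samples = samples)
  b <- background_ld(x, n_reps = 50, n_snps = 60, seed = 3)
  expect_lt(abs(mean(b$replicate_means) - 1 / n_samp), 0.2 / n_samp)
})
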