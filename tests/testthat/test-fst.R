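groups_of <- function(x) list(pepo = group_samples(x, "pepo"),
                              ovifera = group_samples(x, "ovifera"))

test_that("per-site Weir-Cockerham theta handles the canonical cases", {
  # fixed difference, n1 = n2 = 5 -> theta = 1
  x <- make_two_group_cohort(matrix("0/0", 5, 1), matrix("1/1", 5, 1))
  g <- groups_of(x)
  expect_equal(wc_fst_site(x, g$pepo, g$ovifera)$theta, 1)
  # theta = 1 for fixed differences regardless of group sizes
  for (sz in list(c(2, 7), c(5, 3), c(1, 8))) {
    y <- make_two_group_cohort(matrix("1/1", sz[1], 1), matrix("0/0", sz[2], 1))
    gy <- groups_of(y)
    expect_equal(wc_fst_site(y, gy$pepo, gy$ovifera)$theta, 1)
  }
  # identical frequencies and het rates, equal n: a ~ 0, theta <= 0
  z <- make_two_group_cohort(rbind("0/1", "0/1", "1/1", "0/0"),
                             rbind("0/1", "0/1", "1/1", "0/0"))
  gz <- groups_of(z)
  cz <- wc_fst_site(z, gz$pepo, gz$ovifera)
  expect_lt(abs(cz$a), 0.05)
  expect_lte(cz$theta, 0)
  # monomorphic across both groups: all components zero, theta NaN
  m <- make_two_group_cohort(matrix("0/0", 3, 1), matrix("0/0", 3, 1))
  gm <- groups_of(m)
  cm <- wc_fst_site(m, gm$pepo, gm$ovifera)
  expect_equal(c(cm$a, cm$b, cm$c), c(0, 0, 0))
  expect_true(is.nan(cm$theta))
  expect_error(wc_fst_site(x, g$pepo, c(g$ovifera, g$pepo[1])), "overlap")
  expect_error(wc_fst_site(x, character(0), g$ovifera), "non-empty")
})

test_that("per-site theta matches the independent algebra transcription", {
  set.seed(31)
  n_site <- 1000
  gt <- matrix(sample(c("0/0", "0/1", "1/1", "./."), 10 * n_site, TRUE,
                      prob = c(0.35, 0.3, 0.25, 0.1)), 10, n_site)
  x <- make_two_group_cohort(gt[1:6, , drop = FALSE], gt[7:10, , drop = FALSE],
                             pos = seq_len(n_site) * 10L)
  g <- groups_of(x)
  comp <- wc_fst_site(x, g$pepo, g$ovifera)
  for (j in seq_len(n_site)) {
    if (is.na(comp$a[j])) next
    o <- wc_theta_oracle(comp$n1[j], comp$n2[j], comp$p1[j], comp$p2[j],
                         comp$h1[j], comp$h2[j])
    expect_lt(abs(comp$a[j] - o$a), 1e-12)
    expect_lt(abs(comp$b[j] - o$b), 1e-12)
    expect_lt(abs(comp$c[j] - o$c), 1e-12)
    if (!is.nan(comp$theta[j]) && abs(o$theta) <= 1)
      expect_lt(abs(comp$theta[j] - o$theta), 1e-12)
  }
})

test_that("HWE-consistent frequencies reproduce the oracle exactly", {
  # n1 = n2 = 4 diploids, p1 = 0.75, p2 = 0.25, HWE het counts
  g1 <- rbind("1/1", "1/1", "1/0", "0/1")       # 6 alt / 8 -> 0.75, h = 0.5
  g2 <- rbind("0/0", "0/0", "0/1", "1/0")       # 2 alt / 8 -> 0.25, h = 0.5
  x <- make_two_group_cohort(g1, g2)
  g <- groups_of(x)
  comp <- wc_fst_site(x, g$pepo, g$ovifera)
  o <- wc_theta_oracle(4, 4, 0.75, 0.25, 0.5, 0.5)
  expect_equal(comp$theta, o$theta, tolerance = 1e-14)
})

test_that("interval aggregation is ratio-of-sums, with the fixed-gene class", {
  gt1 <- cbind(rbind("0/0", "0/0", "0/0"), rbind("0/1", "0/0", "0/1"))
  gt2 <- cbind(rbind("1/1", "1/1", "1/1"), rbind("0/1", "1/1", "0/1"))
  x <- make_two_group_cohort(gt1, gt2, pos = c(100L, 200L))
  g <- groups_of(x)
  comp <- wc_fst_site(x, g$pepo, g$ovifera)
  iv <- data.frame(chrom = "chr1", start = c(0, 0, 150), end = c(150, 300, 300))
  agg <- fst_aggregate(comp, x$sites, iv)
  # single-site interval equals the site theta
  expect_equal(agg$theta[1], comp$theta[1])
  # ratio-of-sums over both sites differs from the mean of ratios
  ros <- sum(comp$a) / sum(comp$a + comp$b + comp$c)
  expect_equal(agg$theta[2], ros)
  expect_false(isTRUE(all.equal(ros, mean(comp$theta))))
  # fixed interval: all sites fixed differences -> theta 1 and is_fixed
  y <- make_two_group_cohort(matrix("0/0", 3, 2), matrix("1/1", 3, 2),
                             pos = c(100L, 200L))
  gy <- groups_of(y)
  ay <- fst_aggregate(wc_fst_site(y, gy$pepo, gy$ovifera), y$sites,
                      data.frame(chrom = "chr1", start = 0, end = 300))
  expect_equal(ay$theta, 1)
  expect_true(ay$is_fixed)
  # no usable sites -> NaN
  empty <- fst_aggregate(comp, x$sites,
                         data.frame(chrom = "chr1", start = 1000, end = 2000))
  expect_true(is.nan(empty$theta))
})

test_that("Tajima constants reproduce their closed forms at small n", {
  k2 <- tajima_constants(2)
  expect_equal(k2$a1, 1)
  k4 <- tajima_constants(4)
  expect_equal(k4$a1, 1 + 1 / 2 + 1 / 3)
  expect_equal(k4$a2, 1 + 1 / 4 + 1 / 9)
  expect_equal(k4$b1, 5 / 9)
  expect_equal(k4$b2, 2 * (16 + 4 + 3) / (9 * 4 * 3))
  k10 <- tajima_constants(10)
  expect_equal(k10$a1, sum(1 / 1:9))
  expect_equal(k10$b1, 11 / 27)
  expect_equal(k10$c1, k10$b1 - 1 / k10$a1)
  expect_equal(k10$e2, (k10$b2 - 12 / (k10$a1 * 10) + k10$a2 / k10$a1^2) /
                 (k10$a1^2 + k10$a2))
})

test_that("Tajima's D is zero when pi_sum equals S/a1, NaN when monomorphic", {
  # n = 4: 8 singleton sites (pi 1/2) + 3 doubleton sites (pi 2/3):
  # pi_sum = 6 = 11 / a1(4) exactly
  counts <- c(rep(1, 8), rep(2, 3))
  expect_equal(tajima_d_from_counts(4, counts), 0)
  expect_true(is.nan(tajima_d_from_counts(4, integer(0))))
  expect_true(is.nan(tajima_d_from_counts(4, c(0, 4))))  # not segregating
})

test_that("Tajima's D matches an independent transcription and drops", {
  set.seed(12)
  for (k in 1:20) {
    counts <- sample(1:9, 16, TRUE)
    expect_equal(tajima_d_from_counts(10, counts),
                 tajima_d_oracle(10, counts), tolerance = 1e-12)
  }
  # cohort interface: complete-case sites only, n = 2 x diploids
  gt <- rbind(c("0/1", "0/1", "0/0"),
              c("0/1", "./.", "0/0"),
              c("0/0", "1/1", "0/0"))
  x <- make_cohort(gt, pos = c(100L, 200L, 300L),
                   samples = data.frame(accession = c("a", "b", "c"),
                                        morphotype = NA, subspecies = "pepo"))
  td <- tajima_d(x, c("a", "b", "c"))
  expect_equal(td$n, 6L)
  expect_equal(td$S, 1L)                        # site 2 dropped (missing call)
  expect_equal(td$D, tajima_d_oracle(6, 2))     # site 1: c_alt = 2 of 6
  expect_true(is.nan(tajima_d(x, c("a", "b", "c"),
                              list(chrom = "chr1", start = 250,
                                   end = 400))$D))
  expect_warning(d1 <- tajima_d(x, "a"), "n < 4")
  expect_true(is.nan(d1$D))
})

test_that("gene stats assemble pi, D and Fst with degenerate-gene defaults", {
  gt1 <- cbind(rbind("0/0", "0/0", "0/0"), rbind("0/1", "0/1", "0/0"))
  gt2 <- cbind(rbind("1/1", "1/1", "1/1"), rbind("0/0", "0/0", "0/0"))
  x <- make_two_group_cohort(gt1, gt2, pos = c(150L, 1150L))
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t101\t300\t.\t+\t.\tID=gA",
    "chr1\tt\tmRNA\t101\t300\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\tt\texon\t101\t300\t.\t+\t.\tID=e1;Parent=gA.1",
    "chr1\tt\tgene\t2001\t2300\t.\t+\t.\tID=gB",
    "chr1\tt\tmRNA\t2001\t2300\t.\t+\t.\tID=gB.1;Parent=gB",
    "chr1\tt\texon\t2001\t2300\t.\t+\t.\tID=e2;Parent=gB.1"), f)
  genes <- read_gff3(f)
  g <- groups_of(x)
  gs <- gene_stats(x, genes, g)
  # gA holds the fixed-difference site; gB spans no variants
  expect_equal(gs$fst[gs$gene_id == "gA"], 1)
  expect_true(gs$fst_is_fixed[gs$gene_id == "gA"])
  expect_equal(gs$pi_pepo[gs$gene_id == "gB"], 0)
  expect_true(is.nan(gs$tajima_d_pepo[gs$gene_id == "gB"]))
  expect_true(is.nan(gs$fst[gs$gene_id == "gB"]))
  # gene pi equals the windowed kernel restricted to the span
  expect_equal(gs$pi_pepo[1],
               sum(site_pi(x, g$pepo)[x$sites$pos > 100 &
                                        x$sites$pos <= 300]) / 200)
})

test_that("Fst scan applies strict and structural-equality thresholds", {
  st <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   chrom = "c", start = 0, end = 1, n_sites = 1,
                   fst = c(0.80, 0.95, 1 - 1e-15, NaN),
                   fst_is_fixed = c(FALSE, FALSE, TRUE, FALSE))
  sc <- candidate_fst_scan(st, thresholds = 0.80)
  expect_equal(sc$n_scanned, 3L)                 # NaN gene not scanned
  expect_false("g1" %in% sc$above[[1]]$genes)    # 0.80 exactly excluded
  expect_setequal(sc$above[[1]]$genes, c("g2", "g3"))
  expect_equal(sc$fixed$genes, "g3")             # structural equality
  expect_equal(sc$fixed$pct, 100 / 3)
  empty <- candidate_fst_scan(st[0, ])
  expect_equal(empty$n_scanned, 0L)
  expect_equal(empty$fixed$n, 0L)
})

test_that("high-diversity scan flags only strict exceedance, exclusively", {
  st <- data.frame(gene_id = paste0("g", 1:10),
                   pi_pepo = c(rep(0.001, 9), 0.05),
                   pi_ovifera = rep(0.001, 10))
  hs <- high_diversity_scan(st)
  expect_equal(hs$flagged$pepo, "g10")
  expect_equal(hs$flagged$ovifera, character(0))  # all equal: nothing above
  expect_equal(hs$exclusive$pepo, "g10")
  # genes flagged in both subspecies appear in neither exclusive list
  st2 <- st
  st2$pi_ovifera[10] <- 0.05
  hs2 <- high_diversity_scan(st2)
  expect_equal(hs2$exclusive$pepo, character(0))
  expect_equal(hs2$exclusive$ovifera, character(0))
})

test_that("multi-locus theta recovers the Balding-Nichols truth", {
  # condensed recovery check (the acceptance suite runs the full design):
  # 2 x 30 diploids, 3000 sites, F = 0.2 and F = 0
  x <- bn_two_pop_cohort(30, 3000, 0.2, seed = 101)
  g <- groups_of(x)
  comp <- wc_fst_site(x, g$pepo, g$ovifera)
  theta <- sum(comp$a, na.rm = TRUE) /
    sum(comp$a + comp$b + comp$c, na.rm = TRUE)
  expect_gt(theta, 0.17); expect_lt(theta, 0.23)
  x0 <- bn_two_pop_cohort(30, 3000, 0, seed = 102)
  comp0 <- wc_fst_site(x0, g$pepo, g$ovifera)
  theta0 <- sum(comp0$a, na.rm = TRUE) /
    sum(comp0$a + comp0$b + comp0$c, na.rm = TRUE)
  expect_lt(abs(theta0), 0.02)
})
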