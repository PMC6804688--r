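test_that("Balding-Nichols draws reproduce the Beta moments", {
  set.seed(51)
  p <- 0.3; F <- 0.2; n <- 1e5
  draws <- balding_nichols_freqs(rep(p, n), F)
  se <- sqrt(F * p * (1 - p) / n)
  expect_lt(abs(mean(draws) - p), 3 * se)
  expect_lt(abs(var(draws) - F * p * (1 - p)) / (F * p * (1 - p)), 0.10)
  # F -> 0 limit collapses to the ancestral frequency
  expect_equal(balding_nichols_freqs(c(0.2, 0.7), 0), c(0.2, 0.7))
  tiny <- balding_nichols_freqs(rep(0.4, 1000), 1e-4)
  expect_lt(sd(tiny), 0.02)
})

test_that("block haplotypes: exact marginals, intra-block correlation, decay", {
  set.seed(52)
  pos <- seq(100, 49900, by = 100)
  f <- rep(0.4, length(pos))
  H <- simulate_haplotypes(2000, pos, f, block_len = 10000, recomb = 0)
  expect_lt(abs(mean(H) - 0.4), 0.02)            # marginal preserved
  # frequency-matched sites within one block are copies of each other
  blk1 <- which(pos <= 10000)
  expect_true(all(H[, blk1] == H[, blk1[1]]))
  # with recombination, correlation decays across block borders
  H2 <- simulate_haplotypes(4000, pos, f, block_len = 10000, recomb = 0.2)
  r_adj <- cor(H2[, 1], H2[, 101])               # 1 border away (pos 10100)
  r_far <- cor(H2[, 1], H2[, 401])               # 4 borders away
  expect_gt(r_adj, r_far)
  expect_lt(abs(r_adj - 0.8), 0.08)              # (1 - recomb)^1
})

test_that("LD-decay crossing distance shortens with block length", {
  crossings <- vapply(c(20000, 8000, 3000), function(bl) {
    cfg <- sim_config(seed = 53, n_chrom = 2, chrom_len = 200000,
                      n_sites = 2400, block_len = bl,
                      recomb_between_blocks = 0.1, freq_turnover = 0.3,
                      n_fixed_genes = 0, n_high_pi_genes = 0,
                      n_private_high = 0, n_private_moderate = 0,
                      n_triallelic = 0, n_high_missing = 0,
                      missing_rate = 0)
    sim <- simulate_cohort(cfg)
    coh <- filter_sites(mask_genotypes(sim$cohort))$cohort
    pr <- pairwise_r2(coh, max_dist = 200000, max_sites_per_chrom = 600)
    f <- ld_decay_fit(pr, thresholds = 0.5)
    cr <- f$crossings[["r2_below_0.5"]]
    if (is.na(cr)) Inf else cr
  }, numeric(1))
  expect_true(all(diff(crossings) < 0))
})

test_that("pooled-accession calls follow the pooled-fraction thresholds", {
  cl <- pool_calls(c(0, 0.1, 0.15, 0.5, 0.8, 0.9, 1), pool_het_min = 0.15)
  gt <- paste(cl$a, cl$b, sep = "/")
  expect_equal(gt, c("0/0", "0/0", "0/1", "0/1", "0/1", "1/1", "1/1"))
})

test_that("coalescent sample matches the Watterson expectation", {
  set.seed(54)
  # E[S] = theta * a1(n)
  S <- replicate(2000, length(hudson_coalescent(10, 5)))
  expect_lt(abs(mean(S) - 5 * sum(1 / 1:9)) / (5 * sum(1 / 1:9)), 0.05)
  S2 <- replicate(2000, length(hudson_coalescent(2, 3)))
  expect_lt(abs(mean(S2) - 3) / 3, 0.06)
  out <- hudson_coalescent(6, 4)
  expect_true(all(out >= 1 & out <= 5))          # derived counts segregate
  expect_gt(attr(out, "tree_length"), 0)
})

test_that("emitted cohorts are deterministic, self-consistent and parse back", {
  cfg <- sim_config(seed = 77, n_chrom = 2, chrom_len = 60000, n_sites = 800,
                    n_fixed_genes = 2, n_high_pi_genes = 1,
                    n_private_high = 1, n_private_moderate = 1,
                    n_triallelic = 5, n_high_missing = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- emit_cohort(cfg, d1)                     # includes truth self-check
  s2 <- emit_cohort(cfg, d2)
  expect_identical(readLines(s1$paths$vcf), readLines(s2$paths$vcf))
  expect_identical(readLines(s1$paths$fasta), readLines(s2$paths$fasta))
  # files parse through the package readers
  genes <- read_gff3(s1$paths$gff3)
  expect_equal(nrow(genes$index), nrow(s1$genes$index))
  ref <- read_fasta(s1$paths$fasta)
  expect_equal(unname(chrom_lengths(ref)), rep(60000L, 2), ignore_attr = TRUE)
  back <- suppressWarnings(read_vcf(s1$paths$vcf, s1$meta))
  expect_identical(back$gt_a, s1$cohort$gt_a)
  # planted fixed-difference genes: every informative site has a
  # between-subspecies frequency gap of 1 in the truth record
  fixed <- s1$truth$site_class == "fixed_difference"
  expect_true(any(fixed))
  gap <- abs(s1$truth$p_sub[fixed, "pepo"] - s1$truth$p_sub[fixed, "ovifera"])
  expect_equal(gap, rep(1, sum(fixed)))
})

test_that("truth het fractions equal the summary Ho on a confident cohort", {
  cfg <- sim_config(seed = 78, n_chrom = 2, chrom_len = 50000, n_sites = 600,
                    missing_rate = 0, depth_floor = 10, gq_floor = 20,
                    n_fixed_genes = 0, n_high_pi_genes = 0,
                    n_private_high = 0, n_private_moderate = 0,
                    n_triallelic = 0, n_high_missing = 0)
  sim <- simulate_cohort(cfg)
  coh <- filter_sites(mask_genotypes(sim$cohort))$cohort
  expect_equal(n_sites(coh), n_sites(sim$cohort))  # nothing to remove
  s <- accession_summary(coh)
  expect_equal(s$ho, unname(sim$truth$het_fraction[s$accession]))
})

test_that("planted filter violations are generated exactly as configured", {
  cfg <- sim_config(seed = 79, n_chrom = 2, chrom_len = 80000, n_sites = 1500,
                    missing_rate = 0, depth_floor = 10, gq_floor = 20,
                    n_triallelic = 12, n_high_missing = 30,
                    n_fixed_genes = 0, n_high_pi_genes = 0,
                    n_private_high = 0, n_private_moderate = 0)
  sim <- simulate_cohort(cfg)
  fl <- filter_sites(mask_genotypes(sim$cohort))
  expect_equal(fl$report$removed_nonbiallelic, 12L)
  expect_equal(fl$report$removed_missing, 30L)
  # and the removed sites are exactly the planted ones
  kept <- paste(fl$cohort$sites$chrom, fl$cohort$sites$pos)
  tri <- paste(sim$truth$planted_triallelic$chrom,
               sim$truth$planted_triallelic$pos)
  hm <- paste(sim$truth$planted_high_missing$chrom,
              sim$truth$planted_high_missing$pos)
  expect_false(any(c(tri, hm) %in% kept))
})

test_that("inter-chromosome haplotype sites behave as unlinked finite samples", {
  set.seed(55)
  n_hap <- 100
  pos <- seq(100, 20000, by = 100)
  # independent chromosome draws: E[r2] ~ 1/(n - 1) at sample size n
  r2 <- replicate(60, {
    h1 <- simulate_haplotypes(n_hap, c(100, 200), c(0.5, 0.5), 5000, 0.05)
    h2 <- simulate_haplotypes(n_hap, c(100, 200), c(0.5, 0.5), 5000, 0.05)
    cor(h1[, 1], h2[, 1])^2
  })
  expect_lt(abs(mean(r2) - 1 / (n_hap - 1)), 0.25 / n_hap)
})
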