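#!/usr/bin/env Rscript
# Stage 3: nucleotide diversity and linkage disequilibrium.
#
# Windowed per-bp diversity (1 kb and 100 kb) for the whole panel and per
# subspecies, pairwise r2 within 0.5 Mb with the local-polynomial decay fit
# and threshold crossings, 50 kb LD tracks, and the bootstrap background-LD
# estimate (1000 replications x 1000 SNPs) per group.

suppressMessages(library(popgenscan))

seed <- as.integer(Sys.getenv("POPGENSCAN_SEED", "42"))
meta <- read.table("results/cohort/meta.tsv", header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
coh <- filter_sites(mask_genotypes(
  read_vcf("results/cohort/cohort.vcf", meta)))$cohort
chl <- chrom_lengths(read_fasta("results/cohort/ref.fa"))

groups <- list(all = NULL,
               pepo = group_samples(coh, "pepo"),
               ovifera = group_samples(coh, "ovifera"))

for (nm in names(groups)) {
  g <- groups[[nm]]
  for (w in c(1000, 100000)) {
    tr <- window_pi(coh, chl, g, w)
    write_track_table(tr, sprintf("results/pi_%s_%skb.tsv", nm, w / 1000))
    cat(sprintf("pi[%s, %g kb]: mean %.3e per bp over %d windows\n",
                nm, w / 1000, mean(tr$value), nrow(tr)))
  }
  pairs <- pairwise_r2(coh, g, max_dist = 500000, max_sites_per_chrom = 1500)
  fit <- ld_decay_fit(pairs)
  bld <- background_ld(coh, g, n_reps = 1000, n_snps = 1000,
                       seed = seed + match(nm, names(groups)))
  write_track_table(window_ld(pairs, chl), sprintf("results/ld_%s_50kb.tsv", nm))
  cat(sprintf("ld[%s]: %d pairs; fitted r2 at 1 kb %.3f; r2 < 0.4 at %s bp; BLD %.4f\n",
              nm, nrow(pairs), fit$grid$r2_fit[fit$grid$distance == 1000],
              format(fit$crossings[["r2_below_0.4"]]), bld$bld))
  write.table(fit$grid, sprintf("results/ld_decay_%s.tsv", nm), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
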