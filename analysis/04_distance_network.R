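#!/usr/bin/env Rscript
# Stage 4: codominant genetic distance and network export.
#
# Kosman-Leonard pairwise distances over all retained SNPs (pairwise
# deletion of missing loci), exported as a NEXUS DISTANCES block for
# SplitsTree's Neighbor-net, a PHYLIP square matrix, and a neighbor-joining
# summary tree.

suppressMessages(library(popgenscan))

meta <- read.table("results/cohort/meta.tsv", header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
coh <- filter_sites(mask_genotypes(
  read_vcf("results/cohort/cohort.vcf", meta)))$cohort

dm <- distance_matrix(coh)
print(dm)
write_distance_nexus(dm, "results/dist.nexus")
write_distance_phylip(dm, "results/dist.phylip")
nwk <- nj_tree(dm)
writeLines(unclass(nwk), "results/tree.nwk")

ss <- coh$samples$subspecies
within <- mean(dm$d[outer(ss, ss, "==") & upper.tri(dm$d)])
between <- mean(dm$d[outer(ss, ss, "!=") & upper.tri(dm$d)])
cat(sprintf("mean distance within subspecies %.4f, between %.4f\n",
            within, between))
cat("NJ tree:", unclass(nwk), "\n")
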