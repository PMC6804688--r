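test_that("impact tiers are the fixed total map over effect terms", {
  expect_equal(impact_of("stop_gained"), "HIGH")
  expect_equal(impact_of("frameshift_variant"), "HIGH")
  expect_equal(impact_of("splice_donor_variant"), "HIGH")
  expect_equal(impact_of("missense_variant"), "MODERATE")
  expect_equal(impact_of("inframe_deletion"), "MODERATE")
  expect_equal(impact_of("synonymous_variant"), "LOW")
  expect_equal(impact_of("splice_region_variant"), "LOW")
  expect_equal(impact_of(c("intron_variant", "intergenic_variant",
                           "5_prime_UTR_variant")),
               rep("MODIFIER", 3))
})

test_that("region classification follows flank and precedence rules", {
  dir <- withr::local_tempdir()
  paths <- write_toy_files(dir)
  genes <- read_gff3(paths$gff3)
  # 3 kb 5' of the plus-strand gene -> upstream
  expect_equal(classify_region("tc1", 3001, genes)$region, "upstream")
  # 6 kb beyond every gene -> intergenic
  r <- classify_region("tc1", 22000, genes)
  expect_true(is.na(r$gene_id))
  expect_equal(r$region, "intergenic")
  # first intronic base after an exon -> splice site region beats intron
  expect_equal(classify_region("tc1", 6601, genes)$region,
               "splice_site_region")
  # CDS base -> exon; UTR base -> utr5
  expect_equal(classify_region("tc1", 6210, genes)$region, "exon")
  expect_equal(classify_region("tc1", 6100, genes)$region, "utr5")
  # downstream of geneA and (strand-aware) downstream of minus-strand geneB
  both <- classify_region("tc1", 11000, genes)
  expect_equal(nrow(both), 2L)
  expect_setequal(both$region, c("downstream", "downstream"))
})

test_that("toy-genome golden annotation reproduces the hand-derived table", {
  dir <- withr::local_tempdir()
  paths <- write_toy_files(dir)
  genes <- read_gff3(paths$gff3)
  ref <- read_fasta(paths$fasta)
  vars <- rbind(toy_variants(), toy_frameshift())
  x <- make_cohort(matrix("0/1", 2, nrow(vars)), chrom = vars$chrom,
                   pos = vars$pos, ref = vars$ref, alt = vars$alt,
                   masked = TRUE)
  ann <- annotate_variants(x, genes, ref)
  ord <- match(paste(vars$chrom, vars$pos), paste(x$sites$chrom, x$sites$pos))
  for (i in seq_len(nrow(vars))) {
    rec <- ann$effects[ann$effects$site_idx == ord[i], , drop = FALSE]
    rec <- if (is.na(vars$gene[i])) rec else rec[rec$gene_id %in% vars$gene[i], ]
    expect_equal(rec$effect, vars$effect[i], label = paste("pos", vars$pos[i]))
    expect_equal(rec$region, vars$region[i], label = paste("pos", vars$pos[i]))
    expect_equal(rec$impact, vars$impact[i], label = paste("pos", vars$pos[i]))
  }
  # every variant annotated; records bounded by overlapping genes + 1
  expect_true(all(seq_len(n_sites(x)) %in% ann$effects$site_idx))
  expect_true(max(table(ann$effects$site_idx)) <= 3)
  # byte-stable across runs
  ann2 <- annotate_variants(x, genes, ref)
  expect_identical(ann$effects, ann2$effects)
})

test_that("annotation is invariant under reverse-complement mirroring", {
  dir <- withr::local_tempdir()
  fwd <- write_toy_files(dir)
  rev <- write_toy_files(dir, mirror = TRUE)
  genes_f <- read_gff3(fwd$gff3); ref_f <- read_fasta(fwd$fasta)
  genes_r <- read_gff3(rev$gff3); ref_r <- read_fasta(rev$fasta)
  vars <- toy_variants()                         # SNPs only
  mir <- mirror_snps(vars)
  for (i in seq_len(nrow(vars))) {
    if (is.na(vars$gene[i])) next
    m_f <- genes_f$models[[which(genes_f$index$gene_id == vars$gene[i])]]
    m_r <- genes_r$models[[which(genes_r$index$gene_id == vars$gene[i])]]
    e_f <- popgenscan:::best_effect(vars$chrom[i], vars$pos[i], vars$ref[i],
                                    vars$alt[i], m_f, ref_f)
    e_r <- popgenscan:::best_effect(mir$chrom[i], mir$pos[i], mir$ref[i],
                                    mir$alt[i], m_r, ref_r)
    expect_equal(e_r$effect, e_f$effect, label = paste("pos", vars$pos[i]))
    expect_equal(e_r$region, e_f$region, label = paste("pos", vars$pos[i]))
  }
})

test_that("coding-effect classification validates the reference allele", {
  dir <- withr::local_tempdir()
  paths <- write_toy_files(dir)
  genes <- read_gff3(paths$gff3)
  ref <- read_fasta(paths$fasta)
  gA <- genes$models[[which(genes$index$gene_id == "geneA")]]
  expect_error(classify_coding_effect("tc1", 6210, "C", "G", gA, ref),
               "reference mismatch")
  # 2-bp deletion -> frameshift; 3-bp -> inframe deletion
  r3 <- fetch_seq(ref, "tc1", 6300, 6303)
  expect_equal(classify_coding_effect("tc1", 6300, substr(r3, 1, 3),
                                      substr(r3, 1, 1), gA, ref),
               "frameshift_variant")
  expect_equal(classify_coding_effect("tc1", 6300, r3, substr(r3, 1, 1),
                                      gA, ref),
               "inframe_deletion")
  expect_equal(classify_coding_effect("tc1", 6300, substr(r3, 1, 1),
                                      paste0(substr(r3, 1, 1), "ACT"),
                                      gA, ref),
               "inframe_insertion")
})

test_that("Ts/Tv counts transitions over transversions on biallelic SNPs", {
  s <- data.frame(ref = c("A", "C", "A"), alt = c("G", "T", "C"),
                  is_snp = TRUE)
  expect_equal(ts_tv(s), 2)
  s2 <- data.frame(ref = c("A", "A"), alt = c("T", "C"), is_snp = TRUE)
  expect_equal(ts_tv(s2), 0)
  expect_warning(r <- ts_tv(data.frame(ref = "A", alt = "G", is_snp = TRUE)),
                 "no transversions")
  expect_true(is.nan(r))
  # multi-allelic and indel records are excluded from the ratio
  s3 <- data.frame(ref = c("A", "A", "AT"), alt = c("G", "C,T", "A"),
                   is_snp = c(TRUE, TRUE, FALSE))
  expect_warning(expect_true(is.nan(ts_tv(s3))), "no transversions")
})

test_that("Ka/Ks is the non-synonymous to synonymous change-count ratio", {
  eff <- data.frame(site_idx = 1:7,
                    effect = c(rep("missense_variant", 3),
                               rep("synonymous_variant", 4)),
                    impact = c(rep("MODERATE", 3), rep("LOW", 4)))
  expect_equal(ka_ks(eff), 0.75)
  expect_warning(r <- ka_ks(eff[1:3, ]), "no synonymous")
  expect_true(is.nan(r))
})

test_that("group-private effect gene sets follow the presence/absence logic", {
  # site 1: allele only in pepo accessions; site 2: everywhere; site 3: only
  # accession o1
  gt <- rbind(c("0/1", "0/1", "0/0"),
              c("0/1", "1/1", "0/0"),
              c("0/0", "0/1", "0/1"),
              c("0/0", "0/1", "0/0"))
  samples <- data.frame(accession = c("p1", "p2", "o1", "o2"),
                        morphotype = c("mp1", "mp2", "mo1", "mo2"),
                        subspecies = c("pepo", "pepo", "ovifera", "ovifera"))
  x <- make_cohort(gt, pos = c(100L, 200L, 300L), samples = samples,
                   masked = TRUE)
  eff <- data.frame(site_idx = 1:3, gene_id = c("g1", "g2", "g3"),
                    region = "exon",
                    effect = c("missense_variant", "stop_gained",
                               "missense_variant"),
                    impact = c("MODERATE", "HIGH", "MODERATE"))
  sets <- gene_set_comparisons(x, eff, "subspecies")
  expect_equal(sets$private$pepo, "g1")
  expect_equal(sets$private$ovifera, "g3")       # variant in all -> no set
  by_acc <- gene_set_comparisons(x, eff, "accession")
  expect_equal(by_acc$private$o1, "g3")
  expect_equal(by_acc$private$p1, character(0))
  expect_equal(by_acc$pairwise[["p1|p2"]], "g1") # shared by pair, absent out
})
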