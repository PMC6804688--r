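# Hand-built toy genome for the annotation golden test: one chromosome, two
# two-exon coding genes (one per strand), and a panel of variants whose
# effects were derived by hand from the planted codons. The background
# sequence is the repeat "ACCCTG", which contains no ATG, so the only start
# codons are the planted ones.

toy_layout <- list(
  chrom = "tc1", len = 23000,
  # geneA, plus strand: span [6001,8000], exons [6001,6600]+[7001,8000],
  # CDS [6151,6600]+[7001,7852] (1302 bp)
  # geneB, minus strand: same geometry at [14001,16000]
  geneA = list(start = 6001, end = 8000),
  geneB = list(start = 14001, end = 16000)
)

toy_sequence <- function() {
  L <- toy_layout$len
  s <- paste(rep("ACCCTG", ceiling(L / 6)), collapse = "")
  s <- substr(s, 1, L)
  put <- function(s, pos, str) { substr(s, pos, pos + nchar(str) - 1) <- str; s }
  # geneA (+): ATG at CDS start 6151; planted codons 20 (AAA), 30 (GAA),
  # 40 (TAC); stop TAA at CDS end (codon 434, genomic 7850-7852)
  s <- put(s, 6151, "ATG")
  s <- put(s, 6208, "AAA")   # codon 20, CDS 58-60
  s <- put(s, 6238, "GAA")   # codon 30, CDS 88-90
  s <- put(s, 6268, "TAC")   # codon 40, CDS 118-120
  s <- put(s, 7850, "TAA")
  # geneB (-): coding runs right-to-left; CAT at 15850-15852 is the ATG,
  # CTC at 15778-15780 reads GAG (codon 25), TTA at 14151-14153 is the stop
  s <- put(s, 15850, "CAT")
  s <- put(s, 15778, "CTC")
  s <- put(s, 14151, "TTA")
  s
}

toy_gff3_lines <- function(mirror = FALSE) {
  L <- toy_layout$len
  gene_feats <- function(id, g_start, g_end, strand) {
    ex <- rbind(c(g_start, g_start + 599), c(g_start + 1000, g_end))
    cds <- rbind(c(g_start + 150, g_start + 599),
                 c(g_start + 1000, g_start + 1851))
    if (mirror) {
      flip <- function(m) {
        out <- cbind(L - m[, 2] + 1, L - m[, 1] + 1)
        out[order(out[, 1]), , drop = FALSE]
      }
      ex <- flip(ex); cds <- flip(cds)
      tmp <- g_start; g_start <- L - g_end + 1; g_end <- L - tmp + 1
      strand <- if (strand == "+") "-" else "+"
    }
    c(sprintf("tc1\ttoy\tgene\t%d\t%d\t.\t%s\t.\tID=%s", g_start, g_end,
              strand, id),
      sprintf("tc1\ttoy\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.1;Parent=%s",
              g_start, g_end, strand, id, id),
      sprintf("tc1\ttoy\texon\t%d\t%d\t.\t%s\t.\tID=%s.1.e%d;Parent=%s.1",
              ex[, 1], ex[, 2], strand, id, seq_len(nrow(ex)), id),
      sprintf("tc1\ttoy\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.1.c%d;Parent=%s.1",
              cds[, 1], cds[, 2], strand, id, seq_len(nrow(cds)), id))
  }
  c("##gff-version 3",
    gene_feats("geneA", toy_layout$geneA$start, toy_layout$geneA$end, "+"),
    gene_feats("geneB", toy_layout$geneB$start, toy_layout$geneB$end, "-"))
}

# The hand-derived expectation table. `gene` names the gene whose record is
# asserted (NA = the single intergenic record).
toy_variants <- function() {
  seq_ <- toy_sequence()
  base <- function(p) substr(seq_, p, p)
  v <- list(
    list(pos = 6210, alt = "G", gene = "geneA",          # AAA -> AAG (Lys)
         effect = "synonymous_variant", region = "exon", impact = "LOW"),
    list(pos = 6239, alt = "T", gene = "geneA",          # GAA -> GTA (E->V)
         effect = "missense_variant", region = "exon", impact = "MODERATE"),
    list(pos = 6270, alt = "A", gene = "geneA",          # TAC -> TAA
         effect = "stop_gained", region = "exon", impact = "HIGH"),
    list(pos = 7852, alt = "C", gene = "geneA",          # TAA -> TAC
         effect = "stop_lost", region = "exon", impact = "HIGH"),
    list(pos = 6601, alt = "G", gene = "geneA",          # 1st intron base
         effect = "splice_donor_variant", region = "splice_site_region",
         impact = "HIGH"),
    list(pos = 6605, alt = "G", gene = "geneA",          # intron base 5
         effect = "splice_region_variant", region = "splice_site_region",
         impact = "LOW"),
    list(pos = 6800, alt = "G", gene = "geneA",          # deep intron
         effect = "intron_variant", region = "intron", impact = "MODIFIER"),
    list(pos = 6100, alt = "G", gene = "geneA",          # 5' UTR
         effect = "5_prime_UTR_variant", region = "utr5",
         impact = "MODIFIER"),
    list(pos = 3001, alt = "G", gene = "geneA",          # 3 kb before start
         effect = "upstream_gene_variant", region = "upstream",
         impact = "MODIFIER"),
    list(pos = 22000, alt = "G", gene = NA,              # 6 kb past geneB
         effect = "intergenic_variant", region = "intergenic",
         impact = "MODIFIER"),
    list(pos = 15779, alt = "A", gene = "geneB",         # GAG -> GTG (E->V)
         effect = "missense_variant", region = "exon", impact = "MODERATE"),
    list(pos = 15000, alt = "G", gene = "geneB",         # minus-strand donor
         effect = "splice_donor_variant", region = "splice_site_region",
         impact = "HIGH")
  )
  df <- do.call(rbind, lapply(v, function(x)
    data.frame(chrom = "tc1", pos = x$pos, ref = base(x$pos), alt = x$alt,
               gene = x$gene, effect = x$effect, region = x$region,
               impact = x$impact, stringsAsFactors = FALSE)))
  # avoid alt == ref collisions (alt G where reference is already G)
  swap <- df$alt == df$ref
  df$alt[swap] <- ifelse(df$ref[swap] == "C", "T", "C")
  df
}

# Frameshift case kept separate (multi-base ref does not mirror like a SNP).
toy_frameshift <- function() {
  seq_ <- toy_sequence()
  data.frame(chrom = "tc1", pos = 6300, ref = substr(seq_, 6300, 6302),
             alt = substr(seq_, 6300, 6300), gene = "geneA",
             effect = "frameshift_variant", region = "exon",
             impact = "HIGH", stringsAsFactors = FALSE)
}

write_toy_files <- function(dir, mirror = FALSE) {
  seq_ <- toy_sequence()
  if (mirror) seq_ <- revcomp(seq_)
  fa <- file.path(dir, if (mirror) "toy_mirror.fa" else "toy.fa")
  writeLines(c(">tc1", gsub("(.{80})", "\\1\n", seq_)), fa)
  gff <- file.path(dir, if (mirror) "toy_mirror.gff3" else "toy.gff3")
  writeLines(toy_gff3_lines(mirror = mirror), gff)
  list(fasta = fa, gff3 = gff)
}

# Mirror a SNP table onto the reverse-complemented genome.
mirror_snps <- function(df) {
  L <- toy_layout$len
  out <- df
  out$pos <- L - df$pos + 1
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out$ref <- unname(comp[df$ref])
  out$alt <- unname(comp[df$alt])
  out
}
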