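Package: popgenscan
Title: Population-Genomic Diversity, Differentiation and Effect-Annotation
    Scans for Small Resequenced Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-variant-calling population genomics for small multi-accession
    resequencing panels such as the two-subspecies Cucurbita pepo cohort:
    depth/quality genotype masking and site filtering, per-accession variant
    summaries, windowed nucleotide diversity, pairwise linkage disequilibrium
    with local-polynomial decay fitting and a bootstrap background-LD null,
    Kosman-Leonard codominant genetic distance with NEXUS/PHYLIP export,
    per-site and per-gene Weir-Cockerham Fst, Tajima's D selection scans,
    and lightweight variant-effect annotation with impact tiers. Includes a
    synthetic cohort generator (Balding-Nichols differentiation, LD-block
    haplotypes, pooled-accession calling, planted candidate genes and
    effects) and a neutral coalescent sampler for null distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape,
    vcfR,
    Biostrings,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
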