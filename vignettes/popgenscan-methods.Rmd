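---
title: "Methods: population-genomic scans for small resequenced cohorts"
author: "popgenscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-genomic scans for small resequenced cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`popgenscan` implements the post-variant-calling half of a whole-genome
resequencing study of a small, structured plant panel: eight *Cucurbita
pepo* accessions in two subspecies (five *pepo*, three *ovifera*), each
sequenced as a pool of five plants. The package takes a multi-sample VCF,
gene models (GFF3), a reference FASTA and an accession metadata table, and
produces genotype/site filtering, per-accession summaries, windowed
nucleotide diversity, pairwise LD with a decay fit and a bootstrap
background-LD null, Kosman–Leonard codominant distances with NEXUS/PHYLIP
export, per-site and per-gene Weir–Cockerham Fst, per-gene Tajima's D, and
variant-effect annotation with impact tiers. Read cleaning, alignment and
variant calling are out of scope: the pipeline starts at the VCF.

Because the original raw data require cluster-scale mapping and calling,
the package ships a synthetic-cohort generator with machine-readable truth
as its test bed; every statistic is validated against either an independent
oracle or planted truth.

# Filtering model

Genotype calls with read depth strictly below 10 or genotype quality
strictly below 20 are set to missing; afterwards, sites that are not
biallelic or whose missing-call fraction strictly exceeds 30% are removed.
The boundary semantics are deliberate: a call at exactly DP = 10 / GQ = 20
survives, and a site at exactly 30% missing survives. Missingness is
evaluated *after* masking, so a site can be removed purely because masking
silenced its calls. Removal accounting attributes each site to the first
rule that removes it, non-biallelic before missingness, which makes the
filter report deterministic and exactly checkable against planted
violations. Indels pass through filtering (their proportion is reported)
but are excluded from the diversity, LD, Fst, Tajima's D and distance
computations, which operate on the biallelic SNP set.

# Statistics

**Nucleotide diversity.** At a site with `n` called alleles of which `c`
are alternate, `pi = 2 c (n - c) / (n (n - 1))` — the unbiased probability
that two alleles drawn without replacement differ. Sites with fewer than 4
called alleles are undefined (NaN). Window diversity divides the summed
site `pi` by the *full* window length, monomorphic positions counting as
zero; this is the per-bp convention that makes 1 kb and 100 kb windows
comparable. Gene diversity uses the gene span as denominator by default
(exonic length available as an option).

**LD.** Pairwise r² is the squared Pearson correlation of alternate-allele
dosages (0/1/2) over pairwise-complete samples — the phase-free composite
(Rogers–Huff) estimator, appropriate for unphased pooled calls. Pairs are
formed within 0.5 Mb. The decay curve is a tricube-weighted local quadratic
regression (`loess`, degree 2, span 0.3) of r² on distance, evaluated on a
1 kb grid with constant extrapolation outside the observed range and
clamped to [0, 1]; the reported "crossing" of a threshold t is the smallest
grid distance with fitted r² < t. Above 100,000 pairs an evenly spaced
subset of the distance-sorted pairs enters the fit — thinning is
deterministic so runs are reproducible.

**Background LD.** The r² expected between unlinked loci at this sample
size. Each of 1000 replications draws 1000 SNPs genome-wide without
replacement and scores pairs on *different chromosomes* (background means
unlinked, which within-chromosome pairs cannot guarantee), capped at
50,000 pairs per replication; the BLD value is the 97.5th percentile of
the replicate means — the upper bound of the central 95% interval. A
`pooled` mode (97.5th percentile of pooled pair r² values) is exposed
because the phrase "upper interval of the 95% confidence interval of the
r² distribution" admits both readings; the replicate-mean reading is the
default and the one we document. The bootstrap runs on its own seeded RNG
stream and is bit-reproducible.

**Kosman–Leonard distance.** Per locus, similarity is the multiset
intersection of the two unordered diploid allele pairs divided by two
(identical genotype 1, one shared allele 0.5, disjoint 0); distance is one
minus the mean similarity over loci called in both accessions. Missing
loci are deleted pairwise, so each pair may rest on a different locus set;
the per-pair locus counts are reported, and the measure is a semimetric —
the triangle inequality is not guaranteed under missing data. The matrix
is exported as a NEXUS DISTANCES block (SplitsTree's Neighbor-net input)
and PHYLIP square format; a neighbor-joining tree (via `ape`) is provided
as a convenience summary.

**Weir–Cockerham Fst.** The two-population 1984 moment estimator: per-site
variance components `a` (among populations), `b` (among individuals within
populations) and `c` (within individuals), with `theta = a / (a + b + c)`.
Multi-site estimates (windows, genes) combine by ratio of sums — the
estimator's recommended form, stable under rare alleles — and negative
per-site components are retained, since flooring them would bias the ratio
upward. The "Fst = 1.00" gene class is detected structurally as
`|sum(b + c)| < 1e-12` with positive `sum(a)`: at fully fixed genes the
within-population components vanish exactly, and float equality against
1.0 would be fragile. The "Fst > 0.80" threshold is strict, so a gene at
exactly 0.80 is excluded.

**Tajima's D.** Computed per interval per group from complete-case sites
only (a site with any missing call in the group is dropped), which keeps
the sequence count `n = 2 x diploids` constant as the constants
`a1 ... e2` require; per-site-n schemes bias the constants. `D` is NaN
when the interval has no segregating site or `n < 4`. A
derived-allele-count interface (`tajima_d_from_counts`) serves coalescent
null samples directly.

**Effect annotation.** Regions follow the classes intergenic / exon /
intron / splice site region / 5'-UTR / 3'-UTR plus upstream / downstream
within a 5 kb flank (both sides; a variant between two genes can be
upstream of one and downstream of the other, producing one record per
gene). Splice windows follow the conventions of the SnpEff tool family:
the first/last 2 intronic bases are donor/acceptor sites (HIGH), intronic
bases 3–8 and the 3 exonic bases flanking a junction are splice region
(LOW); the "splice site region" tally is the union. Coding SNPs are
classified by rebuilding the affected codon on the coding strand and
translating with the standard nuclear code (start codon ATG only); CDS
indels are frameshift when the length difference is not a codon multiple,
otherwise inframe. Each (variant, gene) pair gets one primary record
carrying the highest-impact candidate effect, ties broken by a fixed
priority order, and the region class is derived from the chosen effect.
Impact tiers are a fixed total map (HIGH: stop gain/loss, start loss,
splice donor/acceptor, frameshift; MODERATE: missense, inframe;
LOW: synonymous, splice region, stop/start retained, UTR start gain;
MODIFIER: everything non-coding). Ka/Ks is a raw count ratio of
non-synonymous to synonymous *changes*, not a per-site-normalized dN/dS —
the genomic summary the study design calls for. Ts/Tv counts A<->G and
C<->T transitions over biallelic SNPs. Impact fractions count each variant
once at its maximal impact; the alternative (once per gene overlap) would
inflate counts at overlapping genes.

# The synthetic cohort generator

The generator emulates the structure the statistics assume, not the
biology of any real genome. Its defaults are the study conditions: 8
accessions (5 *pepo*, 3 *ovifera*), each a pool of 5 plants; 4 chromosomes
of 500 kb; ~20,000 variant sites; depth ~ NegBin(mean 33) matching the
study's 33.5X coverage; GQ ~ clamped Normal(60, 15); 2% missing calls;
transition probability 0.62, giving Ts/Tv near the 1.63 the study reports.

**Differentiation.** Site frequencies follow the Balding–Nichols model:
subspecies frequencies are Beta-distributed around an ancestral frequency
(uniform on [0.05, 0.95]) with differentiation `F_subspecies` (default
0.1), and accession frequencies drift around their subspecies frequency
with `F_morphotype` (default 0.05). These defaults produce clear but
incomplete differentiation, appropriate for testing estimators; planted
features, not the background F, carry the extreme signals.

**LD structure.** Haplotypes follow a block-copying model: each haplotype
holds one latent uniform "backbone" value per 10 kb block, redrawn at
block borders with probability 0.02; a site carries the alternate allele
when the backbone value is below the site frequency. Marginal frequencies
are exact, and frequency-matched sites within a block are perfectly
correlated. Because two indicator variables with unequal frequencies
cannot be fully correlated, frequencies are drawn per *founder segment* —
constant over geometrically many blocks (turnover probability 0.4 per
border, expected segment 25 kb) — so r² is high at short range and decays
along the backbone chain. Segments, not sites, are therefore the
independent units of the genome: a desk-scale genome of 2 Mb holds ~80 of
them. This is the central realism trade-off: paper-scale decay lengths
(r² < 0.4 only beyond 200 kb) would leave too few independent segments for
any between-group statistic to stabilize at 2 Mb, so the default turnover
is faster and the default cohort decays within a few tens of kb. Tests of
distance and Fst recovery use configurations with short blocks and fast
turnover (many independent loci); the decay-shape tests vary `block_len`
and verify the crossing distance shrinks with it. Consequently, passing
tests demonstrate correct estimator behavior under the assumed structure —
not that real *C. pepo* LD looks like the default cohort.

**Pooled calling.** An accession's call at a site is derived from the
pooled alternate fraction f over its 10 plant alleles: hom-ref below 0.15,
hom-alt above 0.85, het otherwise. This reproduces the excess apparent
heterozygosity of pooled sequencing (an accession segregating at any
appreciable frequency is called het) — the reason observed Ho in pooled
panels far exceeds inbred-line expectations. The threshold is a free
parameter with no published counterpart; 0.15 was chosen so that a single
deviant plant (f = 0.1) does not flip a call.

**Planted truth.** The configuration plants, with exact bookkeeping in a
truth record: fixed-difference genes (every site in the gene span fixed
alternate in *pepo*, reference in *ovifera* — the Fst = 1 class),
high-diversity genes (sites at frequency 0.5 in one subspecies,
monomorphic in the other), group-private HIGH/MODERATE effect variants
(codons rewritten in the reference so the alternate allele provably
creates a stop or a missense change, on either strand), tri-allelic sites,
and high-missingness sites (depth forced below the masking threshold in
just over 30% of accessions). Emitted FASTA/GFF3/VCF files are re-read
through the package's own parsers and checked against the truth genotypes
before the generator returns.

**Exactness fixtures.** Filter-exactness checks use `missing_rate = 0`
with depth/quality floors at the masking thresholds, so the planted
violations are provably the only ones and removal counts can be asserted
exactly. The high-diversity recovery check uses ~1000 genes with 10
planted: flagging is defined as exceeding the 99th percentile of the
gene-diversity distribution, so only ~1% of genes can ever be flagged —
with 400 genes the 10 planted could not all clear their own percentile,
which is a property of the percentile definition, not of the estimator.

**Null sampler.** A standard neutral coalescent without recombination
(exponential coalescence times at rate k(k-1)/2, Poisson mutations at
theta/2 per branch-length unit, infinite sites) supplies Tajima's D null
samples; its segregating-site count is validated against the Watterson
expectation `E[S] = theta a1(n)`.

# Numerical choices

- Internal intervals are 0-based half-open; VCF and GFF3 1-based
  conventions are converted at the I/O boundary only.
- Phase is ignored throughout ("/" and "|" both accepted): every estimator
  is phase-free by construction.
- Multi-mRNA genes collapse to the longest CDS, matching per-gene
  statistics that assume one transcript.
- The RNG uses one root seed with per-component child streams derived from
  fixed labels, so adding a stage never perturbs another stage's draws;
  seeded routines save and restore the global RNG state.
- Reported theta values are clamped to [-1, 1]; aggregation uses the
  unclamped components.
- Quantiles (BLD, diversity percentile) use R's default type-7 definition.
- The pair scan caps sites per chromosome (default 1500 in the pipeline)
  by deterministic, evenly spaced thinning; the decay fit caps pairs at
  100,000 the same way. Problem sizes in the test suite (cohorts of
  0.8k–20k sites, 10 seeds for estimator recovery, 500 coalescent
  replicates, 1000-replicate bootstraps) were chosen as the smallest
  designs at which the checked bands are stable.

# Known limitations

- The generator's LD is block-structured with hard segment boundaries;
  real decay curves are smoother, and the default cohort's decay length is
  deliberately shorter than chromosome-scale reality (see above).
- Ka/Ks in the default cohort is ~2.7, the neutral consequence of random
  codon positions; real genomes sit below 1 under purifying selection.
  The generator plants no selection on coding sites, so annotated impact
  fractions are not expected to match any published genome's.
- Kosman–Leonard distances with pairwise deletion can violate the triangle
  inequality; consumers that require a metric should complete-case filter
  first.
- Tajima's D complete-case site selection discards information at high
  missingness; with 3-accession groups (n = 6) the statistic is noisy and
  its published ±2 bounds are approximate.
- The Fst estimator is the two-population form; more than two groups would
  need the general r-population algebra.
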