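---
title: "Detecting sweeps and polygenic adaptation with adaptscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sweeps and polygenic adaptation with adaptscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptscan)
```

## The problem

Complex traits shaped by gene-environment interaction — myopia and its
relationship to sunlight exposure is the motivating example — leave two
very different footprints of selection in population genotype data.
Classic selective sweeps drive individual alleles to high frequency and
drag long homogeneous haplotypes with them; these are visible SNP by SNP.
Polygenic adaptation instead shifts many trait-associated alleles by small,
coordinated amounts that no single-SNP scan can distinguish from drift; it
is detectable only in aggregate, over genes and gene sets. `adaptscan`
implements one coherent pipeline for both signals, plus two follow-up
analyses that connect candidate loci to an environmental driver: a
Bayes-factor test for allele-frequency/environment correlation, and
two-sample Mendelian randomization between an exposure and the trait.

Every stage is backed by a synthetic-data generator with known ground
truth, so the whole pipeline can be exercised, calibrated and
power-tested without any external download.

## Per-SNP selection statistics

**Fst.** Pairwise population differentiation is estimated per SNP with the
Weir & Cockerham (1984) variance-component estimator from diploid genotype
counts: `theta = a / (a + b + c)`, where `a`, `b`, `c` are the
among-population, among-individual and within-individual components and
observed heterozygosity enters `c`. Estimates may legitimately be
negative; SNPs monomorphic in both populations are reported as missing
rather than zero. Samples with a missing call are excluded at that SNP
only (pairwise-complete counts) — haplotype statistics are stricter, see
below.

**PBS.** For a triplet (A, B, C) with focal population A, each pairwise
Fst is transformed to a branch length `T = -ln(1 - Fst)` and

    PBS_A = (T_AB + T_AC - T_BC) / 2,

the allele-frequency change specific to A's branch. Two numerical guards
apply inside the transform only: negative Fst estimates are clamped to 0,
and Fst is capped at `1 - 1e-6` so branch lengths stay finite. The raw
signed Fst is preserved in the `fst_result`, keeping output comparable
with standard Fst tools.

**nSL.** The haplotype statistic compares, at a focal SNP, the mean
pairwise identity-tract length among carriers of the ancestral allele
(`SL_A`) with that among carriers of the derived allele (`SL_D`), with
tract length counted in segregating sites (focal site included) rather
than base pairs — which makes the score robust to recombination-rate
variation. The raw score is `ln(SL_A / SL_D)`; a strongly negative value
means extended homozygosity around the derived allele, the footprint of a
recent sweep. Tracts are truncated at the data edge or after `max_extend`
sites per side (default 100, configurable). Ancestral alleles come from
the VCF `AA` INFO key; SNPs whose annotation matches neither allele are
skipped and counted. Variants carrying any missing call are dropped for
haplotype statistics (but kept for frequency/Fst), reflecting the
different missingness tolerance of the two families of statistics.

Raw nSL depends strongly on the derived-allele frequency, so scores are
standardized within 20 equal-width frequency bins (configurable; the
population standard deviation is used so each bin has mean 0, sd 1
exactly). The conventional selection threshold `|nSL| >= 2` is applied to
these normalized scores — raw values near 2 would be far outside the
plausible range, so the normalized reading is the only sensible one.

## The sweep filter cascade

Candidate sweep SNPs are distilled in stages, each a pure function of its
inputs:

1. **LD pruning** of GWAS SNPs by greedy p-ranked clumping: visit SNPs by
   ascending association p-value and keep each unless its haplotype `r^2`
   with an already-kept SNP within 500 kb exceeds 0.1. Ranked clumping
   (rather than order-dependent pairwise pruning) makes the kept set
   deterministic.
2. **PBS outlier intersection**: per triplet, retain SNPs at or above the
   empirical 99th percentile (linear interpolation; ties retained, since
   the percentile itself is "retained"), then intersect across triplets.
3. **GWAS filter**: strict `p < 5e-3` (the threshold is an exclusive
   bound by its phrasing, unlike the inclusive nSL threshold).
4. **Gene annotation** with union semantics from a user-supplied
   gene-to-SNP map.
5. **Top-SNP nSL filter**: per locus, the member with the smallest GWAS p
   (ties broken by position) must have `|normalized nSL| >= 2`.
6. **Gene-set enrichment** by the upper-tail hypergeometric test with
   Benjamini-Hochberg correction. A hosted enrichment service cannot be
   reproduced offline, so corrected p-values from such services are not
   comparable number for number; the test, universe and correction here
   are fully specified and deterministic.

The percentile and p-value filters commute, so their order does not
matter. Locus definitions are accepted from the caller rather than
invented: clumping rules for "loci" differ between GWAS releases and any
built-in choice would be arbitrary.

## The PBS selection index

The polygenic test asks, gene by gene, whether the observed mean PBS of
the gene's SNPs is higher than random SNP sets of the same size. Because
the gene-size distribution is heavily skewed, each gene's position-sorted
SNPs are first chunked into windows of 11 — the modal gene size in
SNP-count terms. A terminal remainder of at least 6 SNPs becomes its own
bin; smaller remainders merge into the preceding bin. This keeps every
bin between 6 and 16 SNPs, so permutation nulls can be cached per size,
and makes a gene of up to 16 SNPs a single bin.

For a bin of `k` SNPs the index is the permutation tail probability

    index = (1 + #{null draws with mean PBS >= observed}) / (1 + n_perm)

with `n_perm = 100000` by default and each null draw a uniform sample of
`k` distinct SNPs from the genome-wide PBS pool. The add-one correction
keeps the index strictly positive, so FDR adjustment is well defined.
Bins sharing a size share one cached null sample.

Bin indices are Benjamini-Hochberg adjusted and reported alongside the
raw values. The per-gene index is the unweighted mean of the gene's *raw*
bin indices, with significance declared strictly below 0.01. Averaging
raw rather than adjusted indices is a deliberate choice: the raw index is
a calibrated tail probability, so under neutrality almost exactly 1% of
(predominantly single-bin) genes fall below 0.01 — the property the
significance rule implicitly assumes — whereas a mean of BH-adjusted
values concentrates near 1 under the null and would flag essentially
nothing at any threshold. The adjusted-mean variant remains available via
`use_adjusted = TRUE` for sensitivity analyses, and the null calibration
of the default is verified by the test suite (flagged fraction 0.010 ±
0.005 over 10 seeds at 4000 genes and 5000 permutations, with bin indices
passing a Kolmogorov-Smirnov uniformity test).

A linear regression of the per-gene index on gene size, exposed as
`check_size_bias()`, verifies that the binning removed the size confound;
under the null the slope is non-significant in at least 9 of 10 seeds.

**Term testing.** Terms are first restricted to the scored gene universe;
terms with gene counts below the median count are dropped (ties at the
median retained). Redundant terms are pruned by Ward clustering
(`ward.D2`) of `1 - Jaccard` gene-set distances, cutting the tree at 0.5
and keeping the largest term per cluster (ties by lexicographically
smallest id). Jaccard overlap replaces semantic-similarity measures that
require an ontology graph; the interface accepts any user-supplied
distance matrix where an ontology-aware distance is preferred, at the
cost of different cluster memberships. Each surviving term is tested with
a two-sample proportion test — pooled variance, no continuity correction,
one-sided for the term's proportion of significant genes exceeding the
complement's — which matches the enrichment reading of the test; the
complement (rather than all genes) is the background so the two groups
are disjoint.

## Gene-environment Bayes factors

Standardized allele frequencies `y_l = (p_l - pbar) / sqrt(pbar (1 -
pbar))` are modelled as multivariate normal with a population covariance
`omega` capturing shared drift and history. `omega` is estimated from
user-chosen control SNPs as the empirical second-moment matrix, shrunk
toward its own diagonal (weight 0.05 by default) for positive
definiteness. The evidence for an environmental effect on a SNP is

    BF = mean over beta in (-0.3, 0.3) of N(y; beta * env, omega)
         ------------------------------------------------------
                          N(y; 0, omega)

with `env` z-standardized across populations and the uniform prior
integrated over a 201-point equally spaced grid. The estimator is fully
deterministic — a deliberate departure from MCMC-based implementations of
the same model, whose Bayes factors carry run-to-run spread. Absolute
Bayes-factor values are therefore not comparable with MCMC outputs; rank
behaviour is, and the planted-signal separation property (signal vs null
SNPs by Mann-Whitney) is what the package tests. The symmetric grid makes
the Bayes factor invariant to which allele is counted (`y -> -y`).
Latitude is folded to absolute degrees by default, matching a
sunlight-exposure reading of latitude; the flag is configurable. The
prior bound 0.3 and 201 grid points are defaults chosen to cover the
plausible standardized-effect range densely; both are arguments.

## Two-sample Mendelian randomization

Exposure and outcome summary statistics are harmonized to the exposure
effect allele: swapped alleles (directly or as strand complements) negate
the outcome beta, palindromic SNPs (A/T, C/G) are dropped because their
orientation cannot be resolved without frequency information, and every
action is recorded per instrument. The estimators are fixed-effect IVW
(weighted slope through the origin, weights `se_outcome^-2`) and MR-Egger
(weighted least squares with intercept after orienting exposure effects
non-negative); the Egger intercept's t-test (n - 2 df) is the
directional-pleiotropy test. A multiplicative random-effects IVW variant
is available by flag; fixed-effect is the default. Leave-one-out
refitting flags any instrument whose exclusion changes the estimate's
sign or moves it outside the full-set 95% interval.

## What the generators emulate — and what they do not

* `simulate_frequency_table()` draws population frequencies from the
  Balding-Nichols model, chosen because its mean (`p_anc`) and variance
  (`F p (1 - p)`) are known exactly and generator tests can assert them.
  It emulates drift-driven divergence, not demography: no migration,
  bottlenecks, or shared internal branches.
* `simulate_sweep_region()` builds neutral haplotypes as founder-copying
  mosaics (geometric identity tracts) and plants a core haplotype at
  `core_freq`, giving direct control over the tract-length contrast nSL
  measures. It is not a coalescent: allele-frequency spectra and LD decay
  are stylized. Its `plant_core = FALSE` mode yields frequency-matched
  neutral nulls for power experiments.
* `simulate_gene_architecture()` draws gene sizes from a shifted negative
  binomial (shift 2, size 20, prob 2/3) plus a 12% point mass at the
  modal size, making 11 the unambiguous mode with a long right tail
  (mean about 12); terms sample genes uniformly, with one planted term
  flagged as ground truth. Real annotation is clustered and nested;
  random terms overlap far less than GO terms do.
* `simulate_env_correlated_freqs()` adds a linear environmental effect on
  the standardized scale under a chosen covariance; back-transformation
  clips to (0, 1), which slightly flattens extreme SNPs.
* `simulate_mr_instruments()` generates instruments with exact reported
  standard errors — so nominal coverage is a meaningful target — plus
  optional allele flips and palindromes to exercise harmonization.

Passing tests on these generators demonstrates internal correctness and
calibration under the stated models; it does not certify behaviour under
real human demography, ascertainment, or annotation structure.

## Problem sizes and numerical choices

The validation studies run at: 4000 genes x 3 populations x 60 diploid
samples each, 5000 permutations and 10 seeds for null calibration; 50
replicates for the polygenic power study (+2 pooled-SD spikes); 50 sweep
regions among 450 matched neutral regions (200 haplotypes x 201 sites)
for the nSL filter; 500 simulated instrument sets for MR; 20 replicates
of 500 + 500 SNPs across 10 populations for the environmental test.
These sizes give stable Monte-Carlo estimates of each property while
keeping a full run in minutes on one core; the production default of
100000 permutations is retained in `pipeline_config()`.

Tie-breaks and degenerate inputs are handled explicitly: quantile ties at
the PBS threshold are retained; GWAS-p ties at a locus top SNP break by
position; term-pruning ties break by gene count then term id; monomorphic
SNPs yield missing Fst (never 0); bins touching a SNP with missing PBS
are skipped with a logged count; empty harmonization output and singular
covariances raise errors naming the cause.

## Reproducibility

Every generator and every permutation consumes an explicit seed, and the
pipeline derives stage seeds deterministically from one master seed
(`derive_seed()`), so stages can be re-run independently and whole runs
are byte-identical. RNG state of the calling session is saved and
restored around every seeded computation.

## Known limitations

iHS and XP-EHH (genetic-map-based relatives of nSL) are out of scope, as
are multi-population Fst beyond pairs, MCMC estimation of the
environmental covariance model, weighted-median/mode MR estimators, and
ontology-graph-aware term similarity. Headline counts from any specific
published analysis depend on external GWAS releases and annotation
versions and are not reproduction targets; the package's claims are the
calibration and power properties its own test suite computes.
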