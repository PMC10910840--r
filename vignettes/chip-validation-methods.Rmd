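---
title: "Methods: validating a SNP genotyping array against sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: validating a SNP genotyping array against sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipqc)
```

chipqc implements the analytical core of a SNP-chip design and
validation workflow of the kind used for the *Aedes albopictus*
("Aealbo") genotyping array: selecting candidate SNPs for probe tiling,
verifying Mendelian inheritance on laboratory crosses, quantifying
concordance between array and whole-genome sequencing (WGS) genotypes,
correcting functional-annotation bias, quality-controlling wild
samples, and summarising linkage disequilibrium (LD) and population
differentiation. This vignette records the models, the parameter
choices, and the design decisions that were genuinely open.

## Data model

All stages work on a `genotype_dataset`: a samples-by-SNPs matrix of
unphased biallelic calls coded as alternative-allele dosage (0, 1, 2,
`NA` for missing) plus variant and sample metadata tables. Coordinates
are 1-based and fully closed, matching VCF convention, and every
spacing computation uses that convention. Half-called genotypes in
input (one allele missing) are mapped to missing: their information
content is ambiguous for dosage coding and the standard pipelines this
package mirrors discard them. A `platform_callset` adds platform
identity and quality: per-call read depth for sequencing, per-SNP
Fisher linear discriminant (FLD) and call rate for arrays.

## Synthetic data: what it emulates, and what it does not

The generator (`sim_config()`, `simulate_populations()`,
`simulate_cross()`, `simulate_platform_pair()`) exists so every stage
is testable without external downloads. Its defaults are the study
conditions the analyses assume:

* **Population structure.** Five populations (the study's ancestral
  clusters) under the Balding–Nichols model: per SNP an ancestral
  frequency $p \sim U(0.05, 0.5)$, population frequencies
  $p_k \sim \mathrm{Beta}\!\left(p\frac{1-F}{F},
  (1-p)\frac{1-F}{F}\right)$ with $F$ the target $F_{ST}$ (default
  0.10, moderate differentiation), genotypes binomial. Nothing in the
  validation workflow constrains the demographic generator, so the
  standard single-parameter $F_{ST}$ model is used; for $F = 0$ the
  Beta draw is skipped and populations share frequencies exactly.
* **Crosses.** Single-pair matings with 25 offspring (the six
  laboratory crosses average ~25 genotyped offspring). Offspring
  follow the exact Mendelian distribution; an injectable error rate
  replaces a call with a uniform draw from the other two states.
* **Platforms.** The array arm flips calls at a per-SNP error rate
  (default 0.005, matching sub-percent technical-replicate error), with
  10% of probes drawn as poorly separating (FLD < 6) and a tenfold
  error boost there, and per-SNP call rates Beta-distributed near 1.
  The sequencing arm draws per-call depth $d$ (negative binomial,
  default mean 25 and dispersion 0.3 — moderate-coverage WGS with a
  substantial mass of calls below depth 20); homozygotes always read
  correctly, while a heterozygote is called heterozygous only when
  both alleles appear among the $d$ reads, so the miscall probability
  is $(1/2)^{d-1}$ and $d = 0$ yields a missing call. Base-calling
  error is deliberately omitted: allele sampling at heterozygotes is
  the mechanism that dominates chip-vs-WGS disagreement, and omitting
  the second-order term keeps closed forms testable.

The generator draws unlinked loci; it makes no attempt at
linkage-realistic haplotype structure (LD behaviour is exercised with
an explicitly constructed Markov-haplotype panel inside the LD tests),
at site-specific error profiles, or at batch effects. Passing tests
therefore demonstrate calibration of the statistics under their
assumed mechanisms, not robustness to everything real arrays do.

## Probe design

`filter_candidates()` applies, in order, sample missingness (≤ 10%),
SNP missingness (≤ 10%) and a MAF floor (≥ 10%), the filters used to
nominate chip candidates; the order (samples first) mirrors
conventional PLINK practice since no order is dictated.
`enforce_spacing()` implements the "at least 200 bp apart" rule for
coding-region SNPs as a greedy left-to-right scan per scaffold with an
inclusive boundary (a gap of exactly 200 bp satisfies "at least
200 bp"). `allocate_by_category()` fills a tiling budget by category
target fractions, taking top candidates by a caller-supplied ranking
key — a deliberate abstraction of the vendor's proprietary
probe-conversion score — and redistributes the deficit of exhausted
categories proportionally. The published final tiling does not match
any simple target fraction exactly, so the allocation is a stated
approximation of that step, not a reconstruction of the vendor's
selection.

## Segregation testing

For each cross, SNPs with at least one heterozygous parent are
testable. The expected offspring alternative-allele frequency for
parental dosages $g_1, g_2$ is $(g_1 + g_2)/4$, and a two-cell
chi-square on allele counts (df = 1) compares observation with
expectation; the allele-count reading is the default because the
comparison is phrased in terms of allele frequencies (a 3-cell
genotype test is exposed as an option). Missing offspring calls are
dropped from the denominator. Offspring genotypes that are impossible
under the parental pair are tallied per SNP as a Mendelian
inconsistency count; their alleles remain in the observed counts
because the test compares predicted and observed frequencies over all
offspring — excluding them would, under a uniform genotyping-error
model, remove exactly the distorted tail and leave every testable
configuration undistorted, making genotyping error invisible to the
test. P-values of SNPs tested in several families are combined with
Fisher's method ($-2\sum\ln p_i$ against $\chi^2_{2k}$; a single p is
returned unchanged; zeros are clamped to the smallest positive
double), the combined values are Holm-adjusted over all tested SNPs
("Holmes correction" is read as Holm's 1979 step-down), and a SNP
fails below adjusted $p < 0.05$.

Calibration in the test suite uses 5,000 SNPs × 6 families × 25
offspring for the familywise false-failure bound, and 6 families of
2,000 offspring with a 10% error injected into 10% of SNPs for power:
at that family size a SNP distorted in even a single family clears the
Holm threshold, which is the "large family" regime the power property
describes.

## Concordance and the mismatch taxonomy

`pairwise_concordance()` is the percent of identically coded genotypes
over SNPs called in both members of a pair; `replicate_error_rate()`
averages `100 − concordance` over a replicate's pairs. Mismatches
between records of one locus are classified independently as
`ref_allele` (reference alleles differ), `alt_allele` (alternatives
differ) and `zygosity` (both calls present, het/hom status differs) —
the headline per-sample metric is the zygosity mismatch percent, which
is what the published comparison tables tabulate. Population and
overall means are unweighted arithmetic means of per-sample
percentages; this rule reproduces every printed mean of the
platform-comparison table from its per-sample rows (printed values are
rounded half-up, and the tests match that convention).
Allele polarity is harmonised before comparison (swapped ref/alt flips
the dosage and is counted) since the published workflow does not
describe harmonisation; the event count is reported so users can see
when it mattered. `filter_by_metrics()` applies FLD ≥ 6, call rate
≥ 98.5% and read depth ≥ 20; the depth rule defaults to per call in
every compared sample, with a per-SNP-mean option, because the
published filter does not say which was used.

## Annotation bias and proportion-matched subsampling

`category_percents()` reports per-category percentages (exact values
retained internally, two decimals for reporting);
`bias_percent()` is the chip-minus-reference difference. The
largest proportion-matched subsample solves
$N = \left\lfloor \min_c \mathrm{count}_c / p_c \right\rfloor$ over
categories with positive target proportion $p_c$, then allocates
$\mathrm{round}(N p_c)$ with a largest-remainder adjustment (ties by
category order, for determinism). Target proportions are consumed at
the two-decimal precision of the reference report rather than as raw
count ratios: that convention is what reproduces the published
allocation cell-for-cell (raw ratios give a 5,323-SNP synonymous
allocation where the published table prints 5,325). `draw_matched_sets()`
draws independent sets without replacement within category; the
per-set size is a parameter because the published construction does
not pin it.

## Wild-sample quality control

`apply_qc()` runs the cascade in the published order: locus
missingness > 10%; sample missingness > 20%; exact Hardy–Weinberg test
below 1e-5 in any population (the stricter reading of "for each
population"); MAF < 10%; heterozygosity outliers beyond ±4 SD of the
per-sample heterozygous-call fraction (the observed fraction, not the
inbreeding coefficient, which the source does not specify); and
pairwise kinship above 0.354, removing the pair member with higher
missingness. The Hardy–Weinberg p-value is the standard (not mid-p)
exact conditional test: heterozygote counts compatible with the
observed allele counts weighted by
$n!/(n_{AA}!\,n_{Aa}!\,n_{aa}!)\cdot 2^{n_{Aa}}$, normalised, summing
configurations no more probable than the observed one. Kinship uses
the KING-robust estimator
$\varphi = (N_{Aa,Aa} - 2N_{AA,aa})/(N_{Aa}^{(i)} + N_{Aa}^{(j)})$,
chosen because 0.354 ≈ $2^{-3/2}$ is precisely that estimator's
canonical duplicate cutoff.

## Linkage disequilibrium

Scaffolds are concatenated into chromosomes in assembly order
(`chromosome_scale()`), with the caveat — inherited from the
concatenation approach — that inter-scaffold pairs within a chromosome
are included. LD is the composite (genotypic) $r^2$: the squared
Pearson correlation of dosage vectors over co-called samples, the
right choice for unphased genotypes. `ld_decay_curve()` bins all
within-chromosome pairs up to 500 kb into 1 kb bins (defaults sized so
the largest published half-distance, 378 kb, would be measurable) with
MAF ≥ 1% and missingness ≤ 20% filters and at least 6 samples. The
half-distance takes the curve's maximum binned mean as the "original
value" — $r^2$ at distance zero being unobservable — and returns the
first linearly interpolated crossing of half that maximum that holds
for the following bin; monotone or flat curves report "not reached".
The binned-mean-plus-interpolation rule is this package's definition;
the upstream tooling's internal smoothing is undocumented.
`ld_prune()` is a sliding-window greedy pruner (ties broken by lower
MAF, then later position, for determinism).

## Population genetics

`wc_fst()` computes the Weir–Cockerham (1984) variance components
$a, b, c$ per locus with unequal sample sizes and the overall
ratio-of-sums $\hat\theta = \sum a / \sum(a+b+c)$ — ratio-of-sums
rather than mean-of-ratios, and negative per-locus estimates retained
so the sums stay unbiased. The bootstrap resamples loci with
replacement (100 replicates by default), reporting the percentile
interval and the fraction of replicates at or below zero.
`quasi_neutral_set()` keeps intergenic SNPs with locus
$\hat\theta \le 0.2$. Geographic distances are haversine great-circle
kilometres on a 6,378.137 km radius; isolation by distance is the OLS
fit of $F_{ST}/(1-F_{ST})$ on $\ln(\mathrm{km})$ over unique site
pairs (zero-distance pairs dropped), and `mantel_test()` permutes rows
and columns of one matrix jointly with the one-sided add-one p-value
$(1 + \#\{r_\pi \ge r\})/(n_{\mathrm{perm}} + 1)$, the directional
reading appropriate for an isolation-by-distance hypothesis.

## Numerical and testing notes

Problem sizes in the test suite were chosen to exercise the published
calibration claims at desk scale: 5,000 SNPs × 200 samples for
$F_{ST}$ recovery (±0.02 of targets 0.05/0.10/0.20), the exact
Hardy–Weinberg test checked against an independent sequential-pairing
enumeration for every configuration up to 50 individuals, 200-sample
Markov panels for LD half-distance recovery, and 200 replicates of
999-permutation Mantel tests for null uniformity. Statistical
assertions under a fixed seed use tolerances of a few binomial
standard deviations. Known limitations: no phased-haplotype semantics,
no multiallelic or indel support, no recalling from raw array
intensities or sequencing reads, and no ancestry/cluster inference —
all are upstream or downstream of the computations this package owns.
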