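# chipqc

Design and validation analytics for SNP genotyping arrays, written for
the workflow behind the *Aedes albopictus* ("Aealbo") chip: a
tidyverse-style R package covering candidate-SNP selection for probe
tiling, Mendelian segregation testing on laboratory crosses,
technical-replicate and chip-vs-WGS genotype concordance,
functional-annotation bias correction, wild-sample quality control,
linkage-disequilibrium (LD) decay, and population differentiation —
plus a seeded synthetic-data generator so the whole pipeline runs and
is tested without any external data.

It is aimed at researchers building or validating a genotyping array
against sequencing call sets for a non-model organism, and at anyone
who needs the individual statistics as reusable, tested functions.

## What it computes

* **Probe design** — missingness/MAF candidate filters
  (`filter_candidates()`), greedy ≥ 200 bp spacing in coding regions
  (`enforce_spacing()`), and category-targeted tiling allocation with
  deficit redistribution (`allocate_by_category()`).
* **Segregation** — for parents with dosages $g_1, g_2$ the offspring
  alt-allele expectation is $(g_1+g_2)/4$; a df-1 chi-square on allele
  counts, Fisher combination across crosses
  ($-2\sum \ln p_i \sim \chi^2_{2k}$), Holm step-down, failure at
  adjusted $p < 0.05$, and a separate Mendelian-inconsistency tally
  (`run_segregation()`).
* **Concordance** — pairwise genotype concordance with missing-call
  masking, the reference-allele / alternative-allele / zygosity
  mismatch taxonomy, per-sample and per-SNP recurrence accounting with
  unweighted population means (`cross_platform_report()`), and the
  FLD ≥ 6 / call rate ≥ 98.5% / depth ≥ 20 metric filter
  (`filter_by_metrics()`).
* **Annotation bias** — category percentages, chip-minus-WGS bias, and
  the largest proportion-matched subsample
  $N = \lfloor \min_c \mathrm{count}_c/p_c \rfloor$ with
  largest-remainder allocation (`max_matched_subsample()`).
* **Quality control** — exact Hardy–Weinberg test (full enumeration),
  ±4 SD heterozygosity outliers, KING-robust kinship
  $\varphi = (N_{Aa,Aa}-2N_{AA,aa})/(N^{(i)}_{Aa}+N^{(j)}_{Aa})$ with
  the 0.354 duplicate cutoff, assembled into the published six-step
  cascade (`apply_qc()`).
* **LD** — scaffold-to-chromosome coordinates, genotypic $r^2$, binned
  decay curves, half-distance with linear interpolation, and greedy
  $r^2$ pruning (`ld_decay_curve()`, `half_distance()`, `ld_prune()`).
* **Population genetics** — Weir–Cockerham $F_{ST}$ variance
  components with a 100-replicate locus bootstrap (`wc_fst()`),
  quasi-neutral intergenic sets ($\theta \le 0.2$), haversine
  distances, $F_{ST}/(1-F_{ST}) \sim \ln(\mathrm{km})$
  isolation-by-distance regression, and a 999-permutation one-sided
  Mantel test (`mantel_test()`).

Fitted objects follow broom conventions (`tidy()`, `glance()`) and the
main result types have `autoplot()` methods. The printed summary
tables of the published validation study ship as plain-text data
(`aealbo_table1()`, `aealbo_table3()`, `aealbo_table4()`,
`aealbo_chip_counts()`) so the aggregation code can be run against
real numbers.

## Worked example

Simulate a two-population truth set, genotype it on both platforms,
and quantify the chip-vs-WGS disagreement:

```r
library(chipqc)

cfg <- sim_config(n_pops = 2, n_samples_per_pop = 12, n_snps = 2000,
                  target_fst = 0.10, seed = 42L)
truth <- simulate_populations(cfg)
pair  <- simulate_platform_pair(truth, cfg)

cross_platform_report(pair$array, pair$sequencing)
#> <mismatch_report> 24 samples, 2000 shared SNPs
#>   overall zygosity mismatch: 0.97%
```

Most of that 0.97% comes from heterozygotes sequenced at low depth;
the quality-metric filter removes the affected sites (shown here for a
six-sample comparison):

```r
six <- gt_samples(truth)$sample_id[1:6]
filter_by_metrics(gt_subset(pair$array, samples = six),
                  gt_subset(pair$sequencing, samples = six))
#> <metric_filter> 78 of 2000 SNPs retained; zygosity mismatch 0.97% -> 0.00%
```

The Weir–Cockerham estimate recovers the simulation's target
differentiation:

```r
wc_fst(truth, n_boot = 100, seed = 42)
#> <fst_result> theta = 0.1000 over 1955 loci (pop1, pop2)
#>   95% bootstrap CI [0.0925, 0.1064], p(theta <= 0) = 0.000
```

And the proportion-matched subsampling algorithm, applied to the
published chip category counts against the WGS category percentages,
returns the largest bias-corrected chip set:

```r
t4  <- aealbo_table4()
wgs <- category_percents(setNames(t4$wgs_n, t4$category))
max_matched_subsample(setNames(t4$chip_n, t4$category),
                      setNames(wgs$percent_2dp / 100, wgs$category))
#> <matched_subsample> total 39591 SNPs
#> # A tibble: 6 × 5
#>   category       n_source target_fraction n_allocated percent
#>   <chr>             <int>           <dbl>       <int>   <dbl>
#> 1 intron            24387          0.448        17741   44.8
#> 2 intergenic        13758          0.348        13758   34.8
#> 3 synonymous        14323          0.134         5325   13.5
#> 4 non_synonymous     1942          0.0235         930    2.35
#> 5 utr5               3642          0.0237         938    2.37
#> 6 utr3               3697          0.0227         899    2.27
```

The subsample totals 39,591 of the 61,749 chip SNPs (~65%), with
per-category percentages matching the WGS distribution to two
decimals; the intergenic category is the binding one, so it is
allocated in full.

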