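Package: chipqc
Title: Design and Validation Analytics for SNP Genotyping Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and validating single-nucleotide polymorphism
    (SNP) genotyping arrays against whole-genome sequencing (WGS) call sets,
    built around the Aedes albopictus chip-validation workflow. Includes
    candidate-SNP selection for probe design (minor-allele-frequency,
    missingness and spacing filters with category-targeted allocation),
    Mendelian segregation testing on laboratory crosses with Fisher
    combination and Holm correction, technical-replicate and cross-platform
    genotype concordance with a reference/alternative-allele/zygosity
    mismatch taxonomy, functional-annotation bias quantification with
    proportion-matched subsampling, a wild-sample quality-control cascade
    (missingness, minor allele frequency, exact Hardy-Weinberg tests,
    heterozygosity outliers, KING-robust kinship), linkage-disequilibrium
    decay curves with half-distance estimation and r-squared pruning, and
    Weir-Cockerham FST with bootstrap intervals, isolation-by-distance
    regression and Mantel tests. A seeded synthetic-data generator
    (Balding-Nichols populations, Mendelian crosses with injectable error,
    paired array/sequencing call sets with depth-dependent heterozygote
    miscalls) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
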