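#' Published summary tables of the Aealbo chip validation experiments
#'
#' Small plain-text copies of the printed summary tables from the
#' Aedes albopictus ("Aealbo") SNP-chip validation experiments, shipped
#' with the package so the aggregation functions can be exercised against
#' real published numbers:
#'
#' * `aealbo_table1()` — per-sample zygosity mismatch percentages for 18
#'   mosquitoes from two populations (KAT, SAI), for within-platform
#'   comparisons across call-set sizes (`ab`, `ac`, `bc` for the chip;
#'   `yx`, `yw`, `xw` for WGS) and cross-platform comparisons (`ay`,
#'   `bx`, `cw`).
#' * `aealbo_table3()` — pairwise technical-replicate concordances on
#'   the chip, plus random non-replicate pairs.
#' * `aealbo_table4()` — per-category SNP counts from functional
#'   annotation of the WGS and chip call sets.
#' * `aealbo_chip_counts()` — headline chip counts: SNPs tiled, and
#'   SNPs recommended by the genotyping best-practice workflow in the
#'   cross and wild-sample experiments.
#'
#' @return A tibble (see above).
#' @name aealbo_tables
NULL

aealbo_extdata <- function(file) {
  readr::read_tsv(
    system.file("extdata", file, package = "chipqc", mustWork = TRUE),
    show_col_types = FALSE
  )
}

#' @rdname aealbo_tables
#' @export
aealbo_table1 <- function() aealbo_extdata("aealbo_table1_mismatch.tsv")

#' @rdname aealbo_tables
#' @export
aealbo_table3 <- function() aealbo_extdata("aealbo_table3_concordance.tsv")

#' @rdname aealbo_tables
#' @export
aealbo_table4 <- function() aealbo_extdata("aealbo_table4_annotation.tsv")

#' @rdname aealbo_tables
#' @export
aealbo_chip_counts <- function() aealbo_extdata("aealbo_chip_counts.tsv")
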