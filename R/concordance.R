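#' Pairwise genotype concordance between two call vectors
#'
#' Percent of SNPs with identical genotype codes among SNPs called in
#' both vectors; missing calls on either side are excluded from the
#' denominator. With no co-called SNP the concordance is undefined
#' (`NA`).
#'
#' @param calls_a,calls_b Integer call vectors over the same SNP universe.
#' @return Percent identical (0-100), or `NA`.
#' @examples
#' pairwise_concordance(c(0, 1, 2, 1), c(0, 1, 2, 2)) # 75
#' @export
pairwise_concordance <- function(calls_a, calls_b) {
  stopifnot(length(calls_a) == length(calls_b))
  ok <- !is.na(calls_a) & !is.na(calls_b)
  if (!any(ok)) return(NA_real_)
  100 * mean(calls_a[ok] == calls_b[ok])
}

#' All within-group replicate concordances
#'
#' @param dataset A [genotype_dataset] whose samples include technical
#'   replicates.
#' @param groups Named character vector or tibble (`sample_id`, `group`)
#'   mapping samples to replicate groups.
#' @return Tibble: `group`, `sample_a`, `sample_b`, `concordance`.
#' @export
replicate_concordance <- function(dataset, groups) {
  if (is.data.frame(groups)) {
    g <- stats::setNames(groups$group, groups$sample_id)
  } else {
    g <- groups
  }
  out <- list()
  for (grp in unique(g)) {
    members <- names(g)[g == grp]
    if (length(members) < 2) next
    idx <- match(members, dataset$samples$sample_id)
    if (anyNA(idx)) abort("replicate group member missing from dataset.")
    prs <- utils::combn(seq_along(members), 2)
    out[[grp]] <- tibble(
      group = grp,
      sample_a = members[prs[1, ]],
      sample_b = members[prs[2, ]],
      concordance = apply(prs, 2, function(pr) {
        pairwise_concordance(
          dataset$calls[idx[pr[1]], ], dataset$calls[idx[pr[2]], ]
        )
      })
    )
  }
  bind_rows(out)
}

#' Mean error rate for a replicate
#'
#' The mean of `100 - concordance` over the pairwise comparisons
#' involving one technical replicate.
#'
#' @param concordances Numeric vector of pairwise concordance percents.
#' @return Mean error percent.
#' @examples
#' replicate_error_rate(c(99.52, 99.31, 99.67)) # 0.50
#' @export
replicate_error_rate <- function(concordances) {
  stopifnot(length(concordances) >= 1)
  mean(100 - concordances)
}

#' Classify a genotype mismatch between two records of one locus
#'
#' Categories are independent and a pair may carry several:
#' `ref_allele` when the two records' reference alleles differ,
#' `alt_allele` when the alternative alleles differ, and `zygosity` when
#' both calls are non-missing and their heterozygous/homozygous status
#' differs (zygosity is not assessed if either call is missing).
#'
#' @param ref_a,alt_a,ref_b,alt_b Alleles of the two records.
#' @param call_a,call_b Dosage calls (0/1/2/`NA`).
#' @return Character vector, a subset of
#'   `c("ref_allele", "alt_allele", "zygosity")`.
#' @export
classify_mismatch <- function(ref_a, alt_a, ref_b, alt_b, call_a, call_b) {
  out <- character(0)
  if (!identical(ref_a, ref_b)) out <- c(out, "ref_allele")
  if (!identical(alt_a, alt_b)) out <- c(out, "alt_allele")
  if (!is.na(call_a) && !is.na(call_b) &&
    (call_a == 1) != (call_b == 1)) {
    out <- c(out, "zygosity")
  }
  out
}

is_het <- function(x) !is.na(x) & x == 1L

#' Cross-platform mismatch report
#'
#' Compares two call sets over their shared samples and SNPs and
#' assembles the full mismatch accounting: per-sample zygosity-mismatch
#' percent over co-called SNPs (the headline metric), per-sample
#' any-genotype mismatch percent, per-SNP recurrence (number of samples
#' mismatching at each SNP), a recurrence table per population, and
#' record-level reference/alternative-allele mismatch counts. Population
#' means and the overall mean are unweighted arithmetic means of the
#' per-sample percentages. When a shared SNP's ref/alt alleles are
#' swapped between the two sets, the second set's dosages are flipped
#' before comparison and the harmonisation is counted.
#'
#' @param set_a,set_b [genotype_dataset]s (typically [platform_callset]s).
#' @param shared_samples Optional character vector of sample ids present
#'   in both sets (default: the intersection).
#' @return Object of class `mismatch_report` with elements `per_sample`,
#'   `per_snp`, `recurrence`, `summary`, `taxonomy`,
#'   `n_polarity_flipped`.
#' @export
cross_platform_report <- function(set_a, set_b, shared_samples = NULL) {
  samples <- shared_samples %||%
    intersect(set_a$samples$sample_id, set_b$samples$sample_id)
  if (length(samples) < 1) abort("need at least one shared sample.")
  snps <- intersect(set_a$variants$id, set_b$variants$id)
  if (length(snps) == 0) abort("the two call sets share no SNPs.")
  a <- gt_subset(set_a, samples = samples, variants = snps)
  b <- gt_subset(set_b, samples = samples, variants = snps)

  # allele harmonisation
  swapped <- a$variants$ref == b$variants$alt &
    a$variants$alt == b$variants$ref
  if (any(swapped)) {
    b$calls[, swapped] <- 2L - b$calls[, swapped]
  }
  ref_mismatch <- a$variants$ref != b$variants$ref & !swapped
  alt_mismatch <- a$variants$alt != b$variants$alt & !swapped

  co <- !is.na(a$calls) & !is.na(b$calls)
  zyg_mm <- co & (is_het(a$calls) != is_het(b$calls))
  gen_mm <- co & (a$calls != b$calls)

  n_co <- rowSums(co)
  per_sample <- tibble(
    sample_id = samples,
    population = a$samples$population,
    n_cocalled = as.integer(n_co),
    n_zygosity_mismatch = as.integer(rowSums(zyg_mm)),
    pct_zygosity = ifelse(n_co > 0, 100 * rowSums(zyg_mm) / n_co, NA_real_),
    pct_genotype = ifelse(n_co > 0, 100 * rowSums(gen_mm) / n_co, NA_real_)
  )
  per_snp <- tibble(
    snp_id = snps,
    k = as.integer(colSums(zyg_mm)),
    n_cocalled_samples = as.integer(colSums(co))
  )
  recurrence <- purrr::map(
    split(seq_along(samples), a$samples$population),
    function(rows) {
      k <- colSums(zyg_mm[rows, , drop = FALSE])
      mm <- k[k > 0]
      if (length(mm) == 0) return(tibble(
        k = integer(0), n_snps = integer(0), pct_of_mismatching = numeric(0)
      ))
      tb <- table(mm)
      tibble(
        k = as.integer(names(tb)), n_snps = as.integer(tb),
        pct_of_mismatching = 100 * as.integer(tb) / length(mm)
      )
    }
  ) |>
    bind_rows(.id = "population")
  summary <- per_sample |>
    group_by(.data$population) |>
    summarise(
      n_samples = n(),
      mean_pct_zygosity = mean(.data$pct_zygosity),
      mean_pct_genotype = mean(.data$pct_genotype),
      .groups = "drop"
    )
  structure(
    list(
      per_sample = per_sample, per_snp = per_snp, recurrence = recurrence,
      summary = summary,
      overall_mean = mean(per_sample$pct_zygosity),
      overall_mean_genotype = mean(per_sample$pct_genotype),
      taxonomy = tibble(
        category = c("ref_allele", "alt_allele"),
        n_records = c(sum(ref_mismatch), sum(alt_mismatch))
      ),
      n_polarity_flipped = sum(swapped)
    ),
    class = "mismatch_report"
  )
}

#' @export
print.mismatch_report <- function(x, ...) {
  cat(
    "<mismatch_report>", nrow(x$per_sample), "samples,",
    nrow(x$per_snp), "shared SNPs\n"
  )
  cat(sprintf("  overall zygosity mismatch: %.2f%%\n", x$overall_mean))
  invisible(x)
}

#' @export
tidy.mismatch_report <- function(x, ...) x$per_sample

#' @export
glance.mismatch_report <- function(x, ...) {
  tibble(
    n_samples = nrow(x$per_sample),
    n_shared_snps = nrow(x$per_snp),
    overall_pct_zygosity = x$overall_mean,
    overall_pct_genotype = x$overall_mean_genotype,
    n_polarity_flipped = x$n_polarity_flipped
  )
}

#' Population and overall means of per-sample mismatch percentages
#'
#' Aggregates a per-sample mismatch table the way the validation summary
#' tables do: the population mean is the unweighted arithmetic mean of
#' its member samples, and the overall mean is the unweighted mean over
#' all samples.
#'
#' @param per_sample Tibble with a `population` column and one or more
#'   numeric percentage columns.
#' @param cols Character names of the percentage columns to aggregate.
#' @return Tibble with one row per population plus an `"overall"` row.
#' @export
mismatch_percent_summary <- function(per_sample,
                                     cols = setdiff(
                                       names(per_sample),
                                       c("population", "sample",
                                         "sample_id")
                                     )) {
  per_sample <- as_tibble(per_sample)
  by_pop <- per_sample |>
    group_by(.data$population) |>
    summarise(dplyr::across(dplyr::all_of(cols), mean), .groups = "drop")
  overall <- per_sample |>
    summarise(dplyr::across(dplyr::all_of(cols), mean)) |>
    mutate(population = "overall", .before = 1)
  bind_rows(by_pop, overall)
}

#' Filter the shared SNP universe on array and sequencing quality metrics
#'
#' Retains SNPs passing all three probe/site quality thresholds: array
#' FLD >= `fld_min`, array call rate >= `call_rate_min`, and sequencing
#' read depth >= `depth_min` (by default per call, in every compared
#' sample with a genotype call at the site). Returns the retained ids
#' together with the zygosity mismatch rate before and after filtering.
#'
#' @param set_array Array [platform_callset] with `fld` and `call_rate`.
#' @param set_seq Sequencing [platform_callset] with a depth matrix.
#' @param fld_min,call_rate_min,depth_min Thresholds (defaults 6, 0.985,
#'   20).
#' @param depth_rule `"per_call"` (default: every called sample must meet
#'   `depth_min`) or `"snp_mean"` (mean depth across samples).
#' @return List of class `metric_filter`: `retained` ids, `n_before`,
#'   `n_after`, `rate_before`, `rate_after` (overall zygosity mismatch
#'   percents).
#' @export
filter_by_metrics <- function(set_array, set_seq, fld_min = 6,
                              call_rate_min = 0.985, depth_min = 20,
                              depth_rule = c("per_call", "snp_mean")) {
  depth_rule <- match.arg(depth_rule)
  if (is.null(set_array$variants$fld) || is.null(set_array$variants$call_rate)) {
    abort("array set must carry fld and call_rate metrics.")
  }
  if (is.null(set_seq$depth)) abort("sequencing set must carry depth.")
  snps <- intersect(set_array$variants$id, set_seq$variants$id)
  samples <- intersect(set_array$samples$sample_id, set_seq$samples$sample_id)
  arr <- gt_subset(set_array, samples = samples, variants = snps)
  sq <- gt_subset(set_seq, samples = samples, variants = snps)

  ok_fld <- arr$variants$fld >= fld_min
  ok_cr <- arr$variants$call_rate >= call_rate_min
  d <- sq$depth
  d[is.na(sq$calls)] <- NA_integer_ # uncalled sites don't enter comparison
  ok_depth <- if (depth_rule == "per_call") {
    apply(d, 2, function(x) all(x[!is.na(x)] >= depth_min) && any(!is.na(x)))
  } else {
    colMeans(d, na.rm = TRUE) >= depth_min
  }
  retained <- snps[ok_fld & ok_cr & ok_depth]
  if (length(retained) == 0) {
    warn("metric thresholds removed every SNP.")
    return(structure(
      list(retained = character(0), n_before = length(snps), n_after = 0L,
        rate_before = cross_platform_report(arr, sq)$overall_mean,
        rate_after = NA_real_),
      class = "metric_filter"
    ))
  }
  before <- cross_platform_report(arr, sq)
  after <- cross_platform_report(
    gt_subset(arr, variants = retained), gt_subset(sq, variants = retained)
  )
  structure(
    list(
      retained = retained, n_before = length(snps),
      n_after = length(retained),
      rate_before = before$overall_mean, rate_after = after$overall_mean
    ),
    class = "metric_filter"
  )
}

#' @export
print.metric_filter <- function(x, ...) {
  cat(
    "<metric_filter>", x$n_after, "of", x$n_before, "SNPs retained;",
    sprintf("zygosity mismatch %.2f%% -> %.2f%%\n", x$rate_before,
      x$rate_after)
  )
  invisible(x)
}

#' Correlation between mismatches and a quality metric
#'
#' Point-biserial correlation between the mismatch indicator and the
#' metric, plus mismatch rates per metric decile. `"depth"` works at the
#' per-call level (sequencing depth of each compared call), `"fld"` and
#' `"call_rate"` at the per-SNP level (SNP mismatching in at least one
#' sample).
#'
#' @param set_array,set_seq The two [platform_callset]s.
#' @param metric `"depth"`, `"fld"` or `"call_rate"`.
#' @return List of class `metric_correlation`: `correlation`,
#'   `by_decile` tibble (`decile`, `metric_mean`, `mismatch_rate`, `n`).
#' @export
mismatch_metric_correlation <- function(set_array, set_seq,
                                        metric = c("depth", "fld",
                                          "call_rate")) {
  metric <- match.arg(metric)
  snps <- intersect(set_array$variants$id, set_seq$variants$id)
  samples <- intersect(set_array$samples$sample_id,
    set_seq$samples$sample_id)
  arr <- gt_subset(set_array, samples = samples, variants = snps)
  sq <- gt_subset(set_seq, samples = samples, variants = snps)
  co <- !is.na(arr$calls) & !is.na(sq$calls)
  zyg_mm <- co & (is_het(arr$calls) != is_het(sq$calls))
  if (metric == "depth") {
    if (is.null(sq$depth)) abort("sequencing set carries no depth.")
    x <- sq$depth[co]
    y <- as.numeric(zyg_mm[co])
  } else {
    x <- arr$variants[[metric]]
    if (is.null(x)) abort(paste0("array set carries no ", metric, "."))
    y <- as.numeric(colSums(zyg_mm) > 0)
  }
  corr <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    NA_real_
  } else {
    stats::cor(x, y)
  }
  by_decile <- tibble(x = x, y = y) |>
    mutate(decile = dplyr::ntile(.data$x, 10)) |>
    group_by(.data$decile) |>
    summarise(
      metric_mean = mean(.data$x),
      mismatch_rate = mean(.data$y),
      n = n(), .groups = "drop"
    )
  structure(
    list(metric = metric, correlation = corr, by_decile = by_decile),
    class = "metric_correlation"
  )
}
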