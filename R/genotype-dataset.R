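#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows n
NULL

#' Functional-annotation categories recognised throughout the package
#'
#' @format Character vector of the six SnpEff-style categories used on the
#'   chip plus `"unknown"` for unannotated sites.
#' @export
SNP_CATEGORIES <- c(
  "intron", "intergenic", "synonymous", "non_synonymous",
  "utr5", "utr3", "unknown"
)

#' Build a genotype dataset
#'
#' The central container: a samples-by-SNPs matrix of unphased biallelic
#' genotype calls coded as alt-allele dosage (0 = homozygous reference,
#' 1 = heterozygous, 2 = homozygous alternative, `NA` = missing), together
#' with per-variant and per-sample metadata tables. All downstream stages
#' (probe design, segregation, concordance, QC, LD, population genetics)
#' consume this class; none of them reinterprets the 0/2 polarity.
#'
#' @param calls Integer matrix, samples in rows, SNPs in columns, entries in
#'   `{0, 1, 2, NA}`. Row and column names, when present, must agree with
#'   `samples$sample_id` and `variants$id`.
#' @param variants Data frame with one row per SNP: columns `id`, `chrom`,
#'   `pos` (1-based bp), `ref`, `alt`, and optionally `category` (one of
#'   [SNP_CATEGORIES]), `score`, `fld`, `call_rate`. Missing optional columns
#'   are filled with defaults.
#' @param samples Data frame with one row per sample: column `sample_id`,
#'   optionally `population`, `lat`, `lon` (decimal degrees). May be `NULL`,
#'   in which case ids are taken from `rownames(calls)` or generated.
#'
#' @return An object of class `genotype_dataset`.
#' @examples
#' gd <- genotype_dataset(
#'   calls = rbind(s1 = c(0L, 1L), s2 = c(2L, NA)),
#'   variants = tibble::tibble(
#'     id = c("v1", "v2"), chrom = "1", pos = c(100L, 500L),
#'     ref = "A", alt = c("G", "T")
#'   )
#' )
#' gd
#' @export
genotype_dataset <- function(calls, variants, samples = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  variants <- as_tibble(variants)

  if (is.null(samples)) {
    ids <- rownames(calls) %||% paste0("sample", seq_len(nrow(calls)))
    samples <- tibble(sample_id = ids)
  } else {
    samples <- as_tibble(samples)
  }
  if (!"category" %in% names(variants)) variants$category <- "unknown"
  if (!"population" %in% names(samples)) samples$population <- NA_character_

  variants$id <- as.character(variants$id)
  variants$pos <- as.integer(variants$pos)
  samples$sample_id <- as.character(samples$sample_id)
  rownames(calls) <- samples$sample_id
  colnames(calls) <- variants$id

  out <- structure(
    list(calls = calls, variants = variants, samples = samples),
    class = "genotype_dataset"
  )
  validate_genotype_dataset(out)
}

validate_genotype_dataset <- function(x) {
  calls <- x$calls
  v <- x$variants
  s <- x$samples
  if (nrow(calls) != nrow(s)) {
    abort("`calls` rows must match the number of samples.")
  }
  if (ncol(calls) != nrow(v)) {
    abort("`calls` columns must match the number of variants.")
  }
  if (anyDuplicated(s$sample_id)) abort("sample ids must be unique.")
  if (anyDuplicated(v$id)) abort("variant ids must be unique.")
  bad <- setdiff(unique(calls[!is.na(calls)]), 0:2)
  if (length(bad)) {
    abort(paste0("calls must be 0/1/2/NA; found ", paste(bad, collapse = ", ")))
  }
  req <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(v))
  if (length(miss)) {
    abort(paste0("variants lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(v) > 0) {
    if (any(v$pos <= 0, na.rm = TRUE)) abort("positions must be positive.")
    if (any(v$ref == v$alt, na.rm = TRUE)) abort("ref and alt alleles must differ.")
    if (!all(v$category %in% SNP_CATEGORIES)) {
      abort("variant categories must be one of SNP_CATEGORIES.")
    }
  }
  x
}

#' @export
print.genotype_dataset <- function(x, ...) {
  npop <- length(unique(stats::na.omit(x$samples$population)))
  cat(
    "<genotype_dataset> ", nrow(x$calls), " samples x ", ncol(x$calls),
    " SNPs", if (npop > 0) paste0(", ", npop, " population(s)"), "\n",
    sep = ""
  )
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$calls)

#' Number of samples / variants in a dataset
#' @param x A [genotype_dataset].
#' @return Integer count.
#' @export
n_samples <- function(x) nrow(x$calls)

#' @rdname n_samples
#' @export
n_variants <- function(x) ncol(x$calls)

#' Accessors for the parts of a genotype dataset
#'
#' @param x A [genotype_dataset].
#' @return `gt_calls()` the integer call matrix; `gt_variants()` and
#'   `gt_samples()` the metadata tibbles.
#' @export
gt_calls <- function(x) x$calls

#' @rdname gt_calls
#' @export
gt_variants <- function(x) x$variants

#' @rdname gt_calls
#' @export
gt_samples <- function(x) x$samples

#' Subset a genotype dataset by sample and/or variant ids
#'
#' @param x A [genotype_dataset] or [platform_callset].
#' @param samples,variants Character ids (or logical/integer indices) to keep;
#'   `NULL` keeps everything.
#' @return The subset object, same class as the input.
#' @export
gt_subset <- function(x, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(x$calls)) else samples
  vi <- if (is.null(variants)) seq_len(ncol(x$calls)) else variants
  if (is.character(si)) si <- match(si, x$samples$sample_id)
  if (is.character(vi)) vi <- match(vi, x$variants$id)
  if (anyNA(si)) abort("unknown sample id in `samples`.")
  if (anyNA(vi)) abort("unknown variant id in `variants`.")
  x$calls <- x$calls[si, vi, drop = FALSE]
  x$variants <- x$variants[vi, , drop = FALSE]
  x$samples <- x$samples[si, , drop = FALSE]
  if (!is.null(x$depth)) x$depth <- x$depth[si, vi, drop = FALSE]
  x
}

#' Per-variant allele-frequency and missingness summaries
#'
#' `variant_stats()` returns, per SNP, the alternative-allele frequency
#' (computed over non-missing calls), minor allele frequency, and call
#' missingness; `sample_stats()` returns per-sample missingness and the
#' heterozygous-call fraction.
#'
#' @param x A [genotype_dataset].
#' @return A tibble with one row per variant (or sample).
#' @export
variant_stats <- function(x) {
  calls <- x$calls
  n_called <- colSums(!is.na(calls))
  alt <- colSums(calls, na.rm = TRUE)
  p_alt <- unname(ifelse(n_called > 0, alt / (2 * n_called), NA_real_))
  tibble(
    id = x$variants$id,
    n_called = as.integer(n_called),
    alt_freq = p_alt,
    maf = pmin(p_alt, 1 - p_alt),
    missingness = 1 - n_called / nrow(calls)
  )
}

#' @rdname variant_stats
#' @export
sample_stats <- function(x) {
  calls <- x$calls
  n_called <- rowSums(!is.na(calls))
  tibble(
    sample_id = x$samples$sample_id,
    n_called = as.integer(n_called),
    missingness = 1 - n_called / ncol(calls),
    het_frac = ifelse(n_called > 0,
      rowSums(calls == 1, na.rm = TRUE) / n_called, NA_real_
    )
  )
}

#' @export
tidy.genotype_dataset <- function(x, ...) {
  long <- as_tibble(x$calls, rownames = "sample_id")
  tidyr::pivot_longer(long, -"sample_id",
    names_to = "id", values_to = "call"
  ) |>
    left_join(select(x$variants, "id", "chrom", "pos", "category"), by = "id")
}

#' Tag a genotype dataset with platform identity and quality metrics
#'
#' A platform call set is a [genotype_dataset] plus the per-call/per-SNP
#' quality information the validation analyses stratify on: per-call read
#' depth for sequencing platforms; per-SNP Fisher linear discriminant (FLD)
#' score and call rate for array platforms.
#'
#' @param dataset A [genotype_dataset].
#' @param platform `"array"` or `"sequencing"`.
#' @param depth Integer matrix of per-call read depths, same shape as the
#'   call matrix. Required iff `platform = "sequencing"`.
#' @param fld,call_rate Optional numeric per-SNP vectors (array platforms);
#'   stored as variant columns.
#' @return An object of class `platform_callset` (inherits
#'   `genotype_dataset`).
#' @export
platform_callset <- function(dataset, platform = c("array", "sequencing"),
                             depth = NULL, fld = NULL, call_rate = NULL) {
  platform <- match.arg(platform)
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (platform == "sequencing" && is.null(depth)) {
    abort("sequencing call sets require a `depth` matrix.")
  }
  if (platform == "array" && !is.null(depth)) {
    abort("array call sets carry no read depth.")
  }
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    storage.mode(depth) <- "integer"
    if (!identical(dim(depth), dim(dataset$calls))) {
      abort("`depth` must have the same shape as the call matrix.")
    }
    if (any(depth < 0, na.rm = TRUE)) abort("depths must be non-negative.")
  }
  if (!is.null(fld)) {
    if (length(fld) != n_variants(dataset) || any(!is.finite(fld))) {
      abort("`fld` must be finite, one value per SNP.")
    }
    dataset$variants$fld <- as.numeric(fld)
  }
  if (!is.null(call_rate)) {
    if (length(call_rate) != n_variants(dataset) ||
      any(call_rate < 0 | call_rate > 1, na.rm = TRUE)) {
      abort("`call_rate` must lie in [0, 1], one value per SNP.")
    }
    dataset$variants$call_rate <- as.numeric(call_rate)
  }
  dataset$platform <- platform
  dataset$depth <- depth
  class(dataset) <- c("platform_callset", "genotype_dataset")
  dataset
}

#' @export
print.platform_callset <- function(x, ...) {
  cat("<platform_callset> platform:", x$platform, "\n")
  NextMethod()
}
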