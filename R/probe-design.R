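#' Criteria for candidate-SNP selection
#'
#' Defaults mirror array-design practice for this chip: a 10% minor
#' allele frequency floor, 10% missingness ceilings for SNPs and samples,
#' a 200 bp minimum spacing for SNPs in coding regions, and roughly equal
#' thirds of the tiled SNPs on exons, introns and intergenic sequence.
#'
#' @param maf_min Minimum minor allele frequency.
#' @param snp_missing_max Maximum per-SNP missingness.
#' @param sample_missing_max Maximum per-sample missingness.
#' @param min_gap_bp Minimum within-scaffold spacing (inclusive) for SNPs
#'   inside the coding-region mask.
#' @param category_targets Named fractions of the final tiling per
#'   category group.
#' @return A list of class `design_criteria`.
#' @export
design_criteria <- function(maf_min = 0.10, snp_missing_max = 0.10,
                            sample_missing_max = 0.10, min_gap_bp = 200,
                            category_targets = c(
                              exon = 1 / 3, intron = 1 / 3,
                              intergenic = 1 / 3
                            )) {
  if (min_gap_bp < 0) abort("min_gap_bp must be non-negative.")
  if (any(category_targets < 0 | category_targets > 1) ||
    sum(category_targets) > 1 + 1e-9) {
    abort("category_targets must be fractions summing to at most 1.")
  }
  structure(as.list(environment()), class = "design_criteria")
}

#' Filter candidate SNPs on missingness and allele frequency
#'
#' Applies, in order: sample missingness > `sample_missing_max`, SNP
#' missingness > `snp_missing_max`, then MAF < `maf_min` (MAF computed
#' over non-missing calls after sample removal). The report records the
#' removals stage by stage in application order.
#'
#' @param dataset A [genotype_dataset].
#' @param criteria A [design_criteria()].
#' @return List of class `design_result` with elements `data` (the
#'   filtered dataset) and `report` (tibble: stage, n_removed,
#'   n_retained).
#' @export
filter_candidates <- function(dataset, criteria = design_criteria()) {
  removed <- integer(0)
  retained <- integer(0)

  ss <- sample_stats(dataset)
  keep_s <- ss$sample_id[ss$missingness <= criteria$sample_missing_max]
  removed["sample_missingness"] <- n_samples(dataset) - length(keep_s)
  dataset <- gt_subset(dataset, samples = keep_s)
  retained["sample_missingness"] <- n_samples(dataset)

  vs <- variant_stats(dataset)
  keep_v <- vs$id[vs$missingness <= criteria$snp_missing_max]
  removed["snp_missingness"] <- n_variants(dataset) - length(keep_v)
  dataset <- gt_subset(dataset, variants = keep_v)
  retained["snp_missingness"] <- n_variants(dataset)

  vs <- variant_stats(dataset)
  keep_v <- vs$id[!is.na(vs$maf) & vs$maf >= criteria$maf_min]
  removed["maf"] <- n_variants(dataset) - length(keep_v)
  dataset <- gt_subset(dataset, variants = keep_v)
  retained["maf"] <- n_variants(dataset)

  if (n_variants(dataset) == 0) warn("no SNP survived candidate filtering.")
  rep_tbl <- tibble(
    stage = names(removed),
    n_removed = as.integer(removed),
    n_retained = as.integer(retained)
  )
  structure(list(data = dataset, report = rep_tbl), class = "design_result")
}

#' Enforce minimum spacing between SNPs inside a region mask
#'
#' Greedy left-to-right scan per scaffold over the masked SNPs: a SNP is
#' kept iff it lies at least `min_gap_bp` (inclusive boundary) from the
#' last kept masked SNP on the same scaffold. SNPs outside the mask are
#' unaffected and always retained.
#'
#' @param variants Tibble with columns `id`, `chrom`, `pos`.
#' @param min_gap_bp Minimum spacing in bp (inclusive).
#' @param region_mask Logical vector (length `nrow(variants)`) or
#'   character ids marking SNPs subject to spacing; `NULL` masks all.
#' @return Character vector of retained ids.
#' @export
enforce_spacing <- function(variants, min_gap_bp = 200, region_mask = NULL) {
  variants <- as_tibble(variants)
  if (is.null(region_mask)) {
    mask <- rep(TRUE, nrow(variants))
  } else if (is.character(region_mask)) {
    mask <- variants$id %in% region_mask
  } else {
    mask <- as.logical(region_mask)
  }
  keep <- rep(TRUE, nrow(variants))
  for (sc in unique(variants$chrom[mask])) {
    idx <- which(mask & variants$chrom == sc)
    idx <- idx[order(variants$pos[idx])] # stable sort if unsorted
    last <- -Inf
    for (i in idx) {
      if (variants$pos[i] - last >= min_gap_bp) {
        last <- variants$pos[i]
      } else {
        keep[i] <- FALSE
      }
    }
  }
  variants$id[keep]
}

#' Allocate a tiling budget across annotation categories
#'
#' Per category, the top `round(total_n * target)` candidates by
#' `ranking_key` (descending) are taken; when a category cannot fill its
#' quota the deficit is redistributed proportionally across the remaining
#' categories until exhausted.
#'
#' @param candidates Tibble with columns `id`, `category`, and the ranking
#'   column.
#' @param category_targets Named fractions by category.
#' @param ranking_key Name of the numeric ranking column (higher = better);
#'   stands in for proprietary probe-conversion scores.
#' @param total_n Total number of SNPs to select.
#' @return Character vector of selected ids.
#' @export
allocate_by_category <- function(candidates, category_targets,
                                 ranking_key = "score", total_n) {
  candidates <- as_tibble(candidates)
  if (!all(candidates$category %in% names(category_targets))) {
    abort("every candidate must belong to a targeted category.")
  }
  if (total_n > nrow(candidates)) {
    warn("total_n exceeds the candidate count; returning all candidates.")
    return(candidates$id)
  }
  if (total_n <= 0) return(character(0))
  pools <- split(candidates, candidates$category)
  pools <- purrr::map(pools, function(p) {
    p[order(-p[[ranking_key]]), ]
  })
  selected <- purrr::map(pools, function(p) character(0))
  remaining_n <- total_n
  active <- names(category_targets)
  frac <- category_targets
  while (remaining_n > 0 && length(active) > 0) {
    f <- frac[active] / sum(frac[active])
    quota <- round(remaining_n * f)
    # rounding drift: pin the total by adjusting the largest quota
    drift <- remaining_n - sum(quota)
    if (drift != 0) quota[which.max(quota)] <- quota[which.max(quota)] + drift
    taken <- 0
    exhausted <- character(0)
    for (cat in active) {
      pool <- pools[[cat]]
      avail <- if (is.null(pool)) 0 else nrow(pool) - length(selected[[cat]])
      take <- min(quota[[cat]], avail)
      if (take > 0) {
        sel_from <- length(selected[[cat]]) + seq_len(take)
        selected[[cat]] <- c(selected[[cat]], pool$id[sel_from])
        taken <- taken + take
      }
      if (avail <= quota[[cat]]) exhausted <- c(exhausted, cat)
    }
    remaining_n <- remaining_n - taken
    active <- setdiff(active, exhausted)
    if (taken == 0) break
  }
  unname(unlist(selected))
}
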