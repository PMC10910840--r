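#' Functional-category counts and percentages
#'
#' @param counts Named integer vector (or tibble with `category`, `n`)
#'   of SNP counts per functional category.
#' @return Tibble of class `category_counts`: `category`, `n`, `percent`
#'   (exact) and `percent_2dp` (the 2-decimal reporting convention).
#' @examples
#' category_percents(c(intergenic = 13758, intron = 24387))
#' @export
category_percents <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- stats::setNames(counts$n, counts$category)
  }
  total <- sum(counts)
  if (total <= 0) abort("total count must be positive.")
  pct <- unname(100 * counts / total)
  out <- tibble(
    category = names(counts),
    n = as.integer(unname(counts)),
    percent = pct,
    percent_2dp = round(pct, 2)
  )
  class(out) <- c("category_counts", class(out))
  out
}

#' Representation bias of one platform against a reference
#'
#' @param chip_percent,wgs_percent Category percentages (0-100) of the
#'   platform under study and of the reference set.
#' @return `chip_percent - wgs_percent` (vectorised); positive values
#'   mean over-representation on the chip.
#' @examples
#' bias_percent(22.28, 34.75) # -12.47
#' @export
bias_percent <- function(chip_percent, wgs_percent) {
  stopifnot(
    all(chip_percent >= 0 & chip_percent <= 100),
    all(wgs_percent >= 0 & wgs_percent <= 100)
  )
  chip_percent - wgs_percent
}

#' Largest proportion-matched subsample of a categorised SNP pool
#'
#' Finds the largest total `N` such that the pool can supply
#' `N * p_c` SNPs of every category `c` at the reference proportions
#' `p_c`: `N = floor(min_c count_c / p_c)` over categories with positive
#' targets. The per-category allocation is `round(N * p_c)` with a
#' largest-remainder adjustment so the allocation sums exactly to `N`
#' (remainder ties broken by category order). Target percentages are
#' consumed at the stated precision of the reference report — by
#' convention two decimals — which is what reproduces published
#' allocations exactly.
#'
#' @param counts Named integer vector (or `category`/`n` tibble) of the
#'   pool's per-category counts.
#' @param target_fractions Named fractions per category (e.g. `0.3475`
#'   for a reported 34.75%). Categories with zero target are excluded
#'   from the allocation.
#' @return List of class `matched_subsample`: `total`, `allocation`
#'   (tibble `category`, `n_source`, `target_fraction`, `n_allocated`,
#'   `percent`).
#' @export
max_matched_subsample <- function(counts, target_fractions) {
  if (is.data.frame(counts)) {
    counts <- stats::setNames(counts$n, counts$category)
  }
  cats <- names(counts)
  p <- target_fractions[cats]
  if (anyNA(p)) abort("every pool category needs a target fraction.")
  pos <- p > 0
  if (!any(pos)) abort("all target fractions are zero.")
  n_total <- floor(min(counts[pos] / p[pos]))
  alloc <- integer(length(cats))
  if (n_total > 0) {
    raw <- n_total * p[pos]
    base <- floor(raw)
    deficit <- n_total - sum(base)
    if (deficit > 0) {
      rem <- raw - base
      # largest remainder; ties resolved by category order (stable sort)
      extra <- order(-rem)[seq_len(deficit)]
      base[extra] <- base[extra] + 1
    }
    alloc[pos] <- as.integer(base)
    # guaranteed by construction, but guard the cap
    over <- alloc[pos] > counts[pos]
    if (any(over)) {
      excess <- sum(alloc[pos][over] - counts[pos][over])
      alloc[pos][over] <- counts[pos][over]
      slack <- which(!over & alloc[pos] < counts[pos])
      for (j in slack) {
        if (excess == 0) break
        add <- min(excess, counts[pos][j] - alloc[pos][j])
        alloc[pos][j] <- alloc[pos][j] + add
        excess <- excess - add
      }
    }
  }
  structure(
    list(
      total = as.integer(n_total),
      allocation = tibble(
        category = cats,
        n_source = as.integer(counts),
        target_fraction = as.numeric(p),
        n_allocated = alloc,
        percent = if (n_total > 0) 100 * alloc / n_total else rep(0, length(cats))
      )
    ),
    class = "matched_subsample"
  )
}

#' @export
print.matched_subsample <- function(x, ...) {
  cat("<matched_subsample> total", x$total, "SNPs\n")
  print(x$allocation)
  invisible(x)
}

#' Draw proportion-matched SNP sets and their shared fraction
#'
#' Each set is drawn without replacement within category according to the
#' allocation; sets are independent of one another. `shared_fraction()`
#' is the percentage of ids present in every set, relative to the set
#' size.
#'
#' @param pool Tibble with columns `id`, `category`.
#' @param allocation Named integer vector (or the `allocation` tibble of
#'   [max_matched_subsample()]) of SNPs to draw per category.
#' @param k_sets Number of sets.
#' @param seed Optional integer seed.
#' @return List of `k_sets` character-id vectors.
#' @export
draw_matched_sets <- function(pool, allocation, k_sets, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(allocation)) {
    allocation <- stats::setNames(allocation$n_allocated,
      allocation$category)
  }
  pools <- split(pool$id, pool$category)
  purrr::map(seq_len(k_sets), function(i) {
    unlist(purrr::imap(pools, function(ids, cat) {
      k <- allocation[[cat]] %||% 0L
      if (k > length(ids)) {
        abort(paste0("allocation exceeds pool for ", cat))
      }
      sample(ids, k)
    }), use.names = FALSE)
  })
}

#' @rdname draw_matched_sets
#' @param sets List of character-id sets.
#' @return `shared_fraction()`: percent of ids common to all sets.
#' @export
shared_fraction <- function(sets) {
  stopifnot(length(sets) >= 1)
  100 * length(Reduce(intersect, sets)) / length(sets[[1]])
}
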