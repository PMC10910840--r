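#' Chromosome-scale coordinates from a scaffold order
#'
#' Builds cumulative offsets for scaffolds merged into chromosomes in the
#' listed assembly order, so per-scaffold positions can be placed on a
#' single per-chromosome axis.
#'
#' @param scaffold_order Tibble with `scaffold`, `length`, `chrom` in
#'   assembly order (see [read_scaffold_order()]).
#' @return Tibble of class `chromosome_scale`: `scaffold`, `chrom`,
#'   `offset` (bp to add to within-scaffold positions).
#' @export
chromosome_scale <- function(scaffold_order) {
  so <- as_tibble(scaffold_order)
  if (any(so$length <= 0)) abort("scaffold lengths must be positive.")
  if (anyDuplicated(so$scaffold)) abort("each scaffold must appear once.")
  so |>
    group_by(.data$chrom) |>
    mutate(offset = cumsum(.data$length) - .data$length) |>
    ungroup() |>
    select("scaffold", "chrom", "offset") |>
    structure(class = c("chromosome_scale", class(so)))
}

#' Map a scaffold position onto the chromosome scale
#'
#' @param scale A [chromosome_scale()].
#' @param scaffold,pos Scaffold ids and 1-based positions (vectorised).
#' @return Tibble: `chrom`, `pos` (chromosome-scale).
#' @export
map_position <- function(scale, scaffold, pos) {
  i <- match(scaffold, scale$scaffold)
  if (anyNA(i)) {
    abort(paste0("unknown scaffold: ",
      paste(unique(scaffold[is.na(i)]), collapse = ", ")))
  }
  tibble(chrom = scale$chrom[i], pos = scale$offset[i] + as.integer(pos))
}

#' Squared dosage correlation between two loci
#'
#' Composite (genotypic) r-squared: the squared Pearson correlation of
#' the two dosage vectors over samples called at both loci. Undefined
#' (`NA`) with fewer than two co-called samples or zero variance at
#' either locus.
#'
#' @param dosages_i,dosages_j Integer dosage vectors.
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
pairwise_r2 <- function(dosages_i, dosages_j) {
  ok <- !is.na(dosages_i) & !is.na(dosages_j)
  if (sum(ok) < 2) return(NA_real_)
  x <- dosages_i[ok]
  y <- dosages_j[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Binned LD-decay curve per chromosome
#'
#' Filters SNPs on MAF and missingness, then bins the pairwise r-squared
#' of every within-chromosome SNP pair with separation at most
#' `max_dist` into distance bins and reports the per-bin mean. Distances
#' use chromosome-scale coordinates when a [chromosome_scale()] is
#' supplied (scaffold-concatenation caveat: inter-scaffold pairs within
#' a chromosome are included).
#'
#' @param dataset A [genotype_dataset] for a single population.
#' @param max_dist Maximum pair separation in bp (default 500 kb).
#' @param bin_width Bin width in bp (default 1 kb).
#' @param maf_min,miss_max SNP filters (defaults 0.01 and 0.20).
#' @param scale Optional [chromosome_scale()] mapping scaffolds to
#'   chromosomes.
#' @param min_samples Minimum samples required (default 6).
#' @return Tibble of class `ld_curve`: `chrom`, `bin`, `dist_mid`
#'   (bin midpoint, bp), `mean_r2`, `n_pairs`.
#' @export
ld_decay_curve <- function(dataset, max_dist = 5e5, bin_width = 1e3,
                           maf_min = 0.01, miss_max = 0.20, scale = NULL,
                           min_samples = 6) {
  if (n_samples(dataset) < min_samples) {
    abort(paste0("need at least ", min_samples, " samples."))
  }
  vs <- variant_stats(dataset)
  keep <- vs$id[!is.na(vs$maf) & vs$maf >= maf_min &
    vs$missingness <= miss_max]
  dataset <- gt_subset(dataset, variants = keep)
  v <- dataset$variants
  if (!is.null(scale)) {
    mp <- map_position(scale, v$chrom, v$pos)
    v$chrom <- mp$chrom
    v$pos <- mp$pos
  }
  out <- list()
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    if (length(idx) < 2) next
    idx <- idx[order(v$pos[idx])]
    pos <- v$pos[idx]
    r2 <- suppressWarnings(
      stats::cor(dataset$calls[, idx, drop = FALSE],
        use = "pairwise.complete.obs")^2
    )
    prs <- which(upper.tri(r2), arr.ind = TRUE)
    d <- abs(pos[prs[, 2]] - pos[prs[, 1]])
    val <- r2[prs]
    ok <- d <= max_dist & !is.na(val)
    if (!any(ok)) next
    bin <- floor(d[ok] / bin_width) + 1
    tb <- tibble(bin = bin, r2 = val[ok]) |>
      group_by(.data$bin) |>
      summarise(mean_r2 = mean(.data$r2), n_pairs = n(), .groups = "drop")
    tb$chrom <- ch
    tb$dist_mid <- (tb$bin - 0.5) * bin_width
    out[[ch]] <- select(tb, "chrom", "bin", "dist_mid", "mean_r2",
      "n_pairs")
  }
  if (length(out) == 0) {
    warn("no qualifying SNP pair; empty LD curve.")
    return(structure(
      tibble(chrom = character(0), bin = integer(0), dist_mid = numeric(0),
        mean_r2 = numeric(0), n_pairs = integer(0)),
      class = c("ld_curve", class(tibble())), bin_width = bin_width,
      max_dist = max_dist
    ))
  }
  structure(bind_rows(out), class = c("ld_curve", class(tibble())),
    bin_width = bin_width, max_dist = max_dist)
}

#' LD half-distance of a decay curve
#'
#' Let `r_max` be the maximum binned mean r-squared of the chromosome's
#' curve. The half-distance is the smallest distance at which the curve
#' first falls to `r_max / 2` and stays at or below it for the following
#' bin, linearly interpolated between adjacent bin midpoints. Curves
#' that never reach half their maximum report `reached = FALSE` (the
#' half-distance exceeds the curve's span).
#'
#' @param curve An [ld_decay_curve()] result (any tibble with `chrom`,
#'   `dist_mid`, `mean_r2`).
#' @return Tibble: `chrom`, `r_max`, `half_distance` (bp; `NA` when not
#'   reached), `reached`.
#' @export
half_distance <- function(curve) {
  if (nrow(curve) == 0) abort("empty LD curve.")
  purrr::map(split(as_tibble(curve), curve$chrom), function(cv) {
    cv <- arrange(cv, .data$dist_mid)
    r <- cv$mean_r2
    d <- cv$dist_mid
    r_max <- max(r)
    target <- r_max / 2
    n <- length(r)
    hit <- which(r <= target &
      c(r[-1] <= target, TRUE)[seq_len(n)])
    if (length(hit) == 0) {
      return(tibble(chrom = cv$chrom[1], r_max = r_max,
        half_distance = NA_real_, reached = FALSE))
    }
    i <- hit[1]
    hd <- if (i == 1) {
      d[1]
    } else {
      # linear interpolation between the previous bin and the crossing bin
      d[i - 1] + (d[i] - d[i - 1]) * (r[i - 1] - target) / (r[i - 1] - r[i])
    }
    tibble(chrom = cv$chrom[1], r_max = r_max, half_distance = hd,
      reached = TRUE)
  }) |>
    bind_rows()
}

#' Greedy r-squared pruning over sliding windows
#'
#' Within each window of `window` SNPs, the SNP with the most pairwise
#' r-squared values at or above the threshold is removed repeatedly until
#' no within-window pair remains at or above it; the window then advances
#' by `step` SNPs. Ties are broken deterministically: the SNP with the
#' lower MAF is removed first, then the later position.
#'
#' @param dataset A [genotype_dataset].
#' @param r2_threshold Pruning threshold in `(0, 1]` (the workflow uses
#'   0.01 and 0.1).
#' @param window,step Window size and advance, in SNPs.
#' @return Character vector of retained SNP ids.
#' @export
ld_prune <- function(dataset, r2_threshold, window = 50, step = 5) {
  if (r2_threshold <= 0 || r2_threshold > 1) {
    abort("r2_threshold must lie in (0, 1].")
  }
  v <- dataset$variants
  vs <- variant_stats(dataset)
  maf <- stats::setNames(vs$maf, vs$id)
  removed <- character(0)
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    idx <- idx[order(v$pos[idx])]
    start <- 1
    while (start <= length(idx)) {
      win <- idx[start:min(start + window - 1, length(idx))]
      win <- win[!(v$id[win] %in% removed)]
      if (length(win) >= 2) {
        r2 <- suppressWarnings(
          stats::cor(dataset$calls[, win, drop = FALSE],
            use = "pairwise.complete.obs")^2
        )
        diag(r2) <- NA
        repeat {
          high <- !is.na(r2) & r2 >= r2_threshold
          if (!any(high)) break
          deg <- rowSums(high)
          worst <- which(deg == max(deg))
          if (length(worst) > 1) {
            mafs <- maf[v$id[win[worst]]]
            worst <- worst[order(mafs, -v$pos[win[worst]])][1]
          } else {
            worst <- worst[1]
          }
          removed <- c(removed, v$id[win[worst]])
          keep <- setdiff(seq_along(win), worst)
          win <- win[keep]
          r2 <- r2[keep, keep, drop = FALSE]
          if (length(win) < 2) break
        }
      }
      if (start + window - 1 >= length(idx)) break
      start <- start + step
    }
  }
  setdiff(v$id, removed)
}
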