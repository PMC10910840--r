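#' Weir-Cockerham FST with locus bootstrap
#'
#' Per-locus variance components `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals) of the
#' Weir & Cockerham (1984) estimator with unequal sample sizes, and the
#' overall ratio-of-sums estimate `theta = sum(a) / sum(a + b + c)`.
#' Negative per-locus estimates are retained (not truncated) so the sums
#' stay unbiased. Loci monomorphic across all populations are skipped.
#' The bootstrap resamples loci with replacement; the percentile interval
#' and the fraction of replicates at or below zero (the bootstrap p for
#' differentiation) are reported.
#'
#' @param dataset A [genotype_dataset] with population labels (or supply
#'   `pop_labels`).
#' @param pop_labels Optional character vector overriding
#'   `gt_samples(dataset)$population`.
#' @param n_boot Bootstrap replicates over loci (default 100; 0 disables).
#' @param conf Confidence level of the percentile interval.
#' @param seed Optional seed for the bootstrap.
#' @return Object of class `fst_result`: `per_locus` tibble
#'   (`snp_id`, `a`, `b`, `c`, `theta`), `theta` (overall), `boot`
#'   replicate vector, `ci`, `p_boot`, `n_loci_used`.
#'   [generics::tidy()] returns the per-locus table, [generics::glance()]
#'   the overall summary.
#' @export
wc_fst <- function(dataset, pop_labels = NULL, n_boot = 100, conf = 0.95,
                   seed = NULL) {
  pops <- pop_labels %||% dataset$samples$population
  if (anyNA(pops)) abort("every sample needs a population label.")
  pops <- factor(pops)
  if (nlevels(pops) < 2) abort("need at least two populations.")
  comp <- wc_components(dataset$calls, pops)
  keep <- !is.na(comp$a)
  a <- comp$a[keep]
  b <- comp$b[keep]
  cc <- comp$c[keep]
  if (length(a) == 0) abort("no polymorphic locus.")
  theta <- sum(a) / sum(a + b + cc)
  boot <- numeric(0)
  ci <- c(NA_real_, NA_real_)
  p_boot <- NA_real_
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    L <- length(a)
    boot <- vapply(seq_len(n_boot), function(r) {
      i <- sample.int(L, L, replace = TRUE)
      sum(a[i]) / sum(a[i] + b[i] + cc[i])
    }, numeric(1))
    alpha <- 1 - conf
    ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2),
      na.rm = TRUE))
    p_boot <- mean(boot <= 0)
  }
  structure(
    list(
      per_locus = tibble(
        snp_id = dataset$variants$id, a = comp$a, b = comp$b, c = comp$c,
        theta = ifelse(is.na(comp$a), NA_real_,
          comp$a / (comp$a + comp$b + comp$c))
      ),
      theta = theta, boot = boot, ci = ci, p_boot = p_boot, conf = conf,
      n_loci_used = length(a),
      populations = levels(pops)
    ),
    class = "fst_result"
  )
}

# WC84 variance components per locus for a calls matrix and a factor of
# population labels. Returns lists of per-locus a, b, c (NA where the
# locus is monomorphic over all called samples or has < 2 populations).
wc_components <- function(calls, pops) {
  lv <- levels(pops)
  r_all <- length(lv)
  n_mat <- matrix(0, nrow = r_all, ncol = ncol(calls))   # called samples
  p_mat <- matrix(NA_real_, nrow = r_all, ncol = ncol(calls))
  h_mat <- matrix(NA_real_, nrow = r_all, ncol = ncol(calls))
  for (k in seq_len(r_all)) {
    sub <- calls[pops == lv[k], , drop = FALSE]
    n_k <- colSums(!is.na(sub))
    n_mat[k, ] <- n_k
    p_mat[k, ] <- ifelse(n_k > 0, colSums(sub, na.rm = TRUE) / (2 * n_k),
      NA_real_)
    h_mat[k, ] <- ifelse(n_k > 0,
      colSums(sub == 1L, na.rm = TRUE) / n_k, NA_real_)
  }
  a <- b <- cc <- rep(NA_real_, ncol(calls))
  for (j in seq_len(ncol(calls))) {
    ok <- n_mat[, j] > 0
    r <- sum(ok)
    if (r < 2) next
    n_i <- n_mat[ok, j]
    p_i <- p_mat[ok, j]
    h_i <- h_mat[ok, j]
    nbar <- mean(n_i)
    if (nbar <= 1) next
    pbar <- sum(n_i * p_i) / (r * nbar)
    if (pbar == 0 || pbar == 1) next # monomorphic across populations
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a[j] <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
    b[j] <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
      s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc[j] <- hbar / 2
  }
  list(a = a, b = b, c = cc)
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf(
    "<fst_result> theta = %.4f over %d loci (%s)\n", x$theta,
    x$n_loci_used, paste(x$populations, collapse = ", ")
  ))
  if (length(x$boot)) {
    cat(sprintf(
      "  %d%% bootstrap CI [%.4f, %.4f], p(theta <= 0) = %.3f\n",
      round(100 * x$conf), x$ci[1], x$ci[2], x$p_boot
    ))
  }
  invisible(x)
}

#' @export
tidy.fst_result <- function(x, ...) x$per_locus

#' @export
glance.fst_result <- function(x, ...) {
  tibble(
    theta = x$theta, ci_low = x$ci[1], ci_high = x$ci[2],
    p_boot = x$p_boot, n_loci = x$n_loci_used,
    n_boot = length(x$boot)
  )
}

#' Pairwise FST between all population pairs
#'
#' @inheritParams wc_fst
#' @return Tibble: `pop_a`, `pop_b`, `theta`, `ci_low`, `ci_high`,
#'   `p_boot`.
#' @export
pairwise_fst <- function(dataset, n_boot = 100, conf = 0.95, seed = NULL) {
  pops <- dataset$samples$population
  lv <- sort(unique(stats::na.omit(pops)))
  if (length(lv) < 2) abort("need at least two populations.")
  prs <- utils::combn(lv, 2)
  purrr::map(seq_len(ncol(prs)), function(m) {
    keep <- dataset$samples$sample_id[pops %in% prs[, m]]
    fr <- wc_fst(gt_subset(dataset, samples = keep), n_boot = n_boot,
      conf = conf, seed = seed)
    tibble(
      pop_a = prs[1, m], pop_b = prs[2, m], theta = fr$theta,
      ci_low = fr$ci[1], ci_high = fr$ci[2], p_boot = fr$p_boot
    )
  }) |>
    bind_rows()
}

#' Quasi-neutral SNP set
#'
#' Intergenic SNPs whose per-locus FST does not exceed `fst_max`
#' (high-differentiation intergenic sites are excluded as candidate
#' targets of selection).
#'
#' @param variants Variant tibble with a `category` column.
#' @param fst_per_locus Numeric per-locus theta, aligned with `variants`.
#' @param fst_max Exclusion threshold (default 0.2, strict inequality).
#' @return Character vector of retained SNP ids.
#' @export
quasi_neutral_set <- function(variants, fst_per_locus, fst_max = 0.2) {
  stopifnot(nrow(variants) == length(fst_per_locus))
  keep <- variants$category == "intergenic" &
    (is.na(fst_per_locus) | fst_per_locus <= fst_max)
  variants$id[keep]
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6378.137 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees
#'   (vectorised).
#' @return Distance in km.
#' @examples
#' geo_distance_km(0, 0, 0, 1) # 111.32
#' @export
geo_distance_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    abort("coordinates out of range.")
  }
  geosphere::distHaversine(
    cbind(lon1, lat1), cbind(lon2, lat2), r = 6378137
  ) / 1000
}

#' Site-level genetic and geographic distance matrices
#'
#' @param dataset A [genotype_dataset] with population labels and
#'   per-sample coordinates (constant within population).
#' @param n_boot Bootstrap replicates passed to [pairwise_fst()].
#' @param seed Optional seed.
#' @return List of class `distance_matrices`: `genetic` (pairwise FST),
#'   `linearized` (FST / (1 - FST)), `geographic` (km); all symmetric
#'   with zero diagonals.
#' @export
distance_matrices <- function(dataset, n_boot = 0, seed = NULL) {
  fst <- pairwise_fst(dataset, n_boot = n_boot, seed = seed)
  pops <- sort(unique(stats::na.omit(dataset$samples$population)))
  gmat <- matrix(0, length(pops), length(pops),
    dimnames = list(pops, pops))
  for (r in seq_len(nrow(fst))) {
    gmat[fst$pop_a[r], fst$pop_b[r]] <- fst$theta[r]
    gmat[fst$pop_b[r], fst$pop_a[r]] <- fst$theta[r]
  }
  coords <- dataset$samples |>
    filter(!is.na(.data$population)) |>
    group_by(.data$population) |>
    summarise(lat = mean(.data$lat), lon = mean(.data$lon),
      .groups = "drop")
  coords <- coords[match(pops, coords$population), ]
  dmat <- outer(seq_along(pops), seq_along(pops), function(i, j) {
    geo_distance_km(coords$lat[i], coords$lon[i], coords$lat[j],
      coords$lon[j])
  })
  dimnames(dmat) <- list(pops, pops)
  diag(dmat) <- 0
  structure(
    list(genetic = gmat, linearized = gmat / (1 - gmat), geographic = dmat),
    class = "distance_matrices"
  )
}

#' Isolation-by-distance regression
#'
#' Ordinary least squares of linearised FST, `FST / (1 - FST)`, on the
#' natural log of great-circle distance over the unique off-diagonal
#' site pairs. Zero-distance pairs are dropped (log undefined).
#'
#' @param matrices A [distance_matrices()] result, or a list with
#'   `genetic` and `geographic` matrices.
#' @return Tibble: `slope`, `intercept`, `r_squared`, `n_pairs`.
#' @export
ibd_regression <- function(matrices) {
  g <- matrices$genetic
  d <- matrices$geographic
  ut <- upper.tri(g)
  y <- (g / (1 - g))[ut]
  x <- d[ut]
  drop <- x <= 0
  if (any(drop)) {
    message(sum(drop), " zero-distance pair(s) dropped from the IBD fit.")
  }
  y <- y[!drop]
  x <- x[!drop]
  if (length(x) < 3) abort("need at least 3 site pairs.")
  fit <- stats::lm(y ~ log(x))
  tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = summary(fit)$r.squared,
    n_pairs = length(x)
  )
}

#' Mantel permutation test
#'
#' Pearson correlation of the upper-triangle entries of two distance
#' matrices; the null distribution is generated by jointly permuting the
#' rows and columns of the second matrix. The one-sided (greater)
#' p-value uses the add-one convention
#' `p = (1 + #(r_perm >= r)) / (n_perm + 1)`.
#'
#' @param genetic,geographic Conformable symmetric matrices (>= 4 sites).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional seed.
#' @return Tibble: `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(genetic, geographic, n_perm = 999, seed = NULL) {
  stopifnot(identical(dim(genetic), dim(geographic)))
  n <- nrow(genetic)
  if (n < 4) abort("need at least 4 sites.")
  ut <- upper.tri(genetic)
  x <- genetic[ut]
  if (stats::sd(x) == 0 || stats::sd(geographic[ut]) == 0) {
    abort("constant distance matrix; Mantel r undefined.")
  }
  if (!is.null(seed)) set.seed(seed)
  r_obs <- stats::cor(x, geographic[ut])
  r_perm <- vapply(seq_len(n_perm), function(k) {
    i <- sample.int(n)
    stats::cor(x, geographic[i, i][ut])
  }, numeric(1))
  tibble(
    r = r_obs,
    p = (1 + sum(r_perm >= r_obs)) / (n_perm + 1),
    n_perm = n_perm
  )
}
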