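test_that("chromosome scale accumulates offsets within chromosomes only", {
  so <- tibble::tibble(
    scaffold = c("sc1", "sc2", "sc3"),
    length = c(1000, 2000, 5000),
    chrom = c("1", "1", "2")
  )
  cs <- chromosome_scale(so)
  expect_equal(cs$offset, c(0, 1000, 0))
  mp <- map_position(cs, c("sc1", "sc2", "sc3"), c(10, 1, 7))
  expect_equal(mp$pos, c(10, 1001, 7))
  expect_identical(mp$chrom, c("1", "1", "2"))
  expect_error(map_position(cs, "nope", 1), "unknown scaffold")
  expect_error(chromosome_scale(dplyr::mutate(so, length = -length)),
    "positive")
})

test_that("pairwise r2 equals the squared Pearson correlation", {
  expect_equal(pairwise_r2(c(0, 1, 2, 1, 0), c(0, 1, 2, 1, 0)), 1)
  expect_equal(pairwise_r2(c(0, 0, 2, 2), c(2, 2, 0, 0)), 1)
  x <- c(0, 1, 2, 0)
  y <- c(0, 1, 0, 2)
  expect_equal(pairwise_r2(x, y), stats::cor(x, y)^2)
  # hand value: cov = -5/12, var = 11/12 each -> r = -5/11, r^2 = 25/121
  expect_equal(pairwise_r2(x, y), 25 / 121)
  expect_true(is.na(pairwise_r2(c(1, 1, 1), c(0, 1, 2))))
  expect_true(is.na(pairwise_r2(c(0, NA, 1), c(NA, 1, 2))))
})

test_that("a perfectly correlated close pair lands in its distance bin", {
  set.seed(2)
  g <- c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 0L)
  calls <- cbind(g, g, sample(g))
  gd <- make_toy_dataset(calls, pos = c(1000L, 6000L, 400000L))
  cv <- ld_decay_curve(gd, max_dist = 5e5, bin_width = 1e3,
    maf_min = 0.01, min_samples = 6)
  b5 <- cv[cv$bin == 6, ] # distance 5000 -> bin floor(5)+1
  expect_equal(b5$mean_r2, 1)
  # determinism
  cv2 <- ld_decay_curve(gd, max_dist = 5e5, bin_width = 1e3,
    maf_min = 0.01, min_samples = 6)
  expect_identical(cv, cv2)
})

test_that("unlinked SNPs sit near the finite-sample r2 baseline", {
  set.seed(40)
  n <- 50
  calls <- matrix(stats::rbinom(n * 200, 2, 0.5), nrow = n)
  gd <- make_toy_dataset(calls,
    pos = sort(sample.int(2e5, 200)))
  cv <- ld_decay_curve(gd, max_dist = 2e5, bin_width = 2e5)
  # E[r^2] for independent loci ~ 1/(n-1)
  expect_lt(abs(sum(cv$mean_r2 * cv$n_pairs) / sum(cv$n_pairs) -
    1 / (n - 1)), 0.01)
})

test_that("half-distance recovers the decay constant of synthetic curves", {
  d <- seq(500, 5e5 - 500, by = 1000)
  curve <- tibble::tibble(
    chrom = "1", bin = seq_along(d), dist_mid = d,
    mean_r2 = 0.8 * exp(-d / 1e5), n_pairs = 100L
  )
  hd <- half_distance(curve)
  # r_max sits at the first bin, so the crossing is near ln(2) * 100 kb
  expect_true(hd$reached)
  expect_lt(abs(hd$half_distance - log(2) * 1e5) / (log(2) * 1e5), 0.02)

  # constant curve never halves
  flat <- dplyr::mutate(curve, mean_r2 = 0.3)
  expect_false(half_distance(flat)$reached)

  # two-bin trace: (1.0, 0.5) halves exactly at the second midpoint
  two <- tibble::tibble(chrom = "1", bin = 1:2, dist_mid = c(500, 1500),
    mean_r2 = c(1, 0.5), n_pairs = 10L)
  expect_equal(half_distance(two)$half_distance, 1500)
})

test_that("half-distance recovers lambda ln 2 on a correlated panel", {
  # dosage correlation exp(-d/1e5) -> r^2 decay constant 5e4; r_max sits
  # at the first bin midpoint, shifting the crossing by half a bin. A
  # single 300 kb realization carries correlated r^2 noise, so the
  # recovery is asserted on the mean over five panel realizations.
  expected <- log(2) * 5e4 + 1e3
  hds <- purrr::map_dbl(1:5, function(s) {
    set.seed(s)
    positions <- sort(sample.int(3e5, 220))
    gd <- correlated_genotype_panel(200, positions, decay_bp = 1e5,
      seed = s)
    cv <- ld_decay_curve(gd, max_dist = 3e5, bin_width = 2e3,
      min_samples = 6)
    hd <- half_distance(cv)
    expect_true(hd$reached)
    hd$half_distance
  })
  expect_lt(abs(mean(hds) - expected) / expected, 0.10)
})

test_that("half-distance estimates shrink with sample size on average", {
  set.seed(23)
  positions <- sort(sample.int(2e5, 150))
  hds <- vapply(c(12, 120), function(n) {
    hd <- purrr::map_dbl(1:4, function(r) {
      gd <- correlated_genotype_panel(n, positions, decay_bp = 8e4,
        seed = 100 * n + r)
      half_distance(ld_decay_curve(gd, max_dist = 2e5,
        bin_width = 1e4))$half_distance
    })
    mean(hd)
  }, numeric(1))
  expect_gt(hds[1], hds[2])
})

test_that("pruning removes exactly the hand-traced culprits", {
  # v1 ~ v2 duplicated, v3 independent; threshold 0.1
  g <- c(0L, 1L, 2L, 1L, 0L, 2L, 0L, 1L, 2L, 1L)
  set.seed(3)
  calls <- cbind(g, g, stats::rbinom(10, 2, 0.5))
  gd <- make_toy_dataset(calls, pos = c(100L, 200L, 300L))
  kept <- ld_prune(gd, 0.99)
  expect_length(intersect(kept, c("v1", "v2")), 1)
  expect_true("v3" %in% kept)

  # all pairs below threshold: everything retained
  set.seed(7)
  indep <- make_toy_dataset(matrix(stats::rbinom(300, 2, 0.5), nrow = 30),
    pos = as.integer(1:10 * 100))
  expect_length(ld_prune(indep, 0.99), 10)

  expect_error(ld_prune(gd, 0), "0, 1")
})

test_that("no retained within-window pair exceeds the prune threshold", {
  set.seed(28)
  gd <- correlated_genotype_panel(80, sort(sample.int(5e4, 60)),
    decay_bp = 2e4, seed = 28)
  for (thr in c(0.1, 0.4)) {
    kept <- ld_prune(gd, thr, window = 60, step = 10)
    sub <- gt_subset(gd, variants = kept)
    if (n_variants(sub) >= 2) {
      r2 <- suppressWarnings(stats::cor(gt_calls(sub),
        use = "pairwise.complete.obs")^2)
      diag(r2) <- NA
      expect_true(all(r2 < thr, na.rm = TRUE))
    }
  }
})
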