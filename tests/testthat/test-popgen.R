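test_that("theta hits the boundary cases exactly", {
  # two populations fixed for opposite alleles -> theta = 1
  calls <- rbind(
    matrix(0L, nrow = 10, ncol = 20), matrix(2L, nrow = 10, ncol = 20)
  )
  gd <- make_toy_dataset(calls, pops = rep(c("A", "B"), each = 10))
  fst <- wc_fst(gd, n_boot = 0)
  expect_equal(fst$theta, 1)

  # shared frequencies -> theta near zero
  set.seed(61)
  p <- stats::runif(2000, 0.1, 0.9)
  calls0 <- t(replicate(100, stats::rbinom(2000, 2, p)))
  gd0 <- make_toy_dataset(calls0, pops = rep(c("A", "B"), each = 50))
  expect_lt(abs(wc_fst(gd0, n_boot = 0)$theta), 0.01)
})

test_that("per-locus components match the independent WC84 oracle", {
  # stated toy configuration: pop1 9/1/0, pop2 0/1/9
  counts <- rbind(c(9, 1, 0), c(0, 1, 9))
  oracle <- wc_oracle_one_locus(counts)
  calls <- rbind(
    matrix(rep(c(rep(0L, 9), 1L), 1), ncol = 1),
    matrix(rep(c(1L, rep(2L, 9)), 1), ncol = 1)
  )
  gd <- make_toy_dataset(calls, pops = rep(c("A", "B"), each = 10))
  fst <- wc_fst(gd, n_boot = 0)
  pl <- tidy(fst)
  expect_equal(pl$a, unname(oracle["a"]), tolerance = 1e-12)
  expect_equal(pl$b, unname(oracle["b"]), tolerance = 1e-12)
  expect_equal(pl$c, unname(oracle["c"]), tolerance = 1e-12)
  expect_equal(fst$theta,
    unname(oracle["a"] / sum(oracle)), tolerance = 1e-12)
})

test_that("components agree with the oracle on random configurations", {
  set.seed(71)
  for (i in 1:300) {
    n_pop <- sample(2:4, 1)
    counts <- matrix(sample(0:15, n_pop * 3, replace = TRUE),
      nrow = n_pop)
    counts[rowSums(counts) == 0, 1] <- 1
    p_all <- (2 * counts[, 3] + counts[, 2]) / (2 * rowSums(counts))
    pbar <- sum(rowSums(counts) * p_all) / sum(rowSums(counts))
    if (pbar == 0 || pbar == 1) next
    calls <- do.call(rbind, lapply(seq_len(n_pop), function(k) {
      matrix(rep(c(rep(0L, counts[k, 1]), rep(1L, counts[k, 2]),
        rep(2L, counts[k, 3])), 1), ncol = 1)
    }))
    pops <- rep(paste0("P", seq_len(n_pop)), rowSums(counts))
    gd <- make_toy_dataset(calls, pops = pops)
    fst <- suppressWarnings(wc_fst(gd, n_boot = 0))
    oracle <- wc_oracle_one_locus(counts)
    expect_equal(fst$per_locus$a, unname(oracle["a"]), tolerance = 1e-10)
    expect_equal(fst$per_locus$b, unname(oracle["b"]), tolerance = 1e-10)
    expect_equal(fst$per_locus$c, unname(oracle["c"]), tolerance = 1e-10)
  }
})

test_that("bootstrap interval brackets the estimate and p reflects theta", {
  cfg <- sim_config(n_pops = 2, n_samples_per_pop = 30, n_snps = 800,
    target_fst = 0.10, seed = 10L)
  gd <- simulate_populations(cfg)
  fst <- wc_fst(gd, n_boot = 100, seed = 99)
  expect_lte(fst$ci[1], fst$theta)
  expect_gte(fst$ci[2], fst$theta)
  expect_equal(fst$p_boot, 0) # clearly differentiated
  expect_length(fst$boot, 100)
})

test_that("quasi-neutral sets keep only low-FST intergenic SNPs", {
  v <- tibble::tibble(
    id = paste0("v", 1:10),
    category = rep(c("intergenic", "intron"), 5)
  )
  theta <- c(0, 0.21, 0.1, 0.5, 0.2, 0.05, NA, 0, 0.3, 0.1)
  kept <- quasi_neutral_set(v, theta)
  # intergenic rows are 1,3,5,7,9 with theta 0, 0.1, 0.2, NA, 0.3
  expect_setequal(kept, c("v1", "v3", "v5", "v7"))
})

test_that("great-circle distances follow the haversine closed form", {
  expect_equal(geo_distance_km(0, 0, 0, 0), 0)
  expect_equal(geo_distance_km(0, 0, 0, 1), 2 * pi * 6378.137 / 360,
    tolerance = 1e-6)
  expect_equal(geo_distance_km(12, 40, -33, 151),
    geo_distance_km(-33, 151, 12, 40))
  expect_error(geo_distance_km(91, 0, 0, 0), "out of range")
})

test_that("IBD regression reproduces a hand least-squares fit", {
  pops <- c("a", "b", "c", "d")
  d <- matrix(0, 4, 4, dimnames = list(pops, pops))
  d[upper.tri(d)] <- c(10, 20, 40, 80, 160, 320)
  d <- d + t(d)
  # y exactly linear in log distance -> R^2 = 1, slope recovered
  g_lin <- matrix(0, 4, 4, dimnames = list(pops, pops))
  y <- 0.01 + 0.002 * log(d[upper.tri(d)])
  g_lin[upper.tri(g_lin)] <- y / (1 + y) # so that y = fst/(1-fst)
  g_lin <- g_lin + t(g_lin)
  fit <- suppressWarnings(
    ibd_regression(list(genetic = g_lin, geographic = d))
  )
  expect_equal(fit$slope, 0.002, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # hand OLS on an arbitrary 4-site fixture
  g <- matrix(0, 4, 4, dimnames = list(pops, pops))
  g[upper.tri(g)] <- c(0.01, 0.05, 0.03, 0.08, 0.02, 0.06)
  g <- g + t(g)
  fit2 <- ibd_regression(list(genetic = g, geographic = d))
  yy <- (g / (1 - g))[upper.tri(g)]
  xx <- log(d[upper.tri(d)])
  beta <- sum((xx - mean(xx)) * (yy - mean(yy))) / sum((xx - mean(xx))^2)
  expect_equal(fit2$slope, beta, tolerance = 1e-12)
  expect_equal(fit2$intercept, mean(yy) - beta * mean(xx),
    tolerance = 1e-12)

  # independence -> R^2 near zero on average (seeded single draw)
  set.seed(9)
  g_r <- matrix(0, 4, 4)
  g_r[upper.tri(g_r)] <- stats::runif(6, 0, 0.1)
  g_r <- g_r + t(g_r)
  expect_lt(ibd_regression(list(genetic = g_r, geographic = d))$r_squared,
    0.9)
})

test_that("Mantel statistic and permutation p behave canonically", {
  set.seed(35)
  n <- 6
  base <- matrix(stats::runif(n * n), n, n)
  base <- (base + t(base)) / 2
  diag(base) <- 0
  double <- 2 * base
  mt <- mantel_test(base, double, n_perm = 99, seed = 1)
  expect_equal(mt$r, 1)
  expect_equal(mt$p, 1 / 100) # minimum attainable with 99 permutations

  # consistent relabeling leaves r unchanged
  perm <- sample(n)
  mt2 <- mantel_test(base[perm, perm], double[perm, perm], n_perm = 99,
    seed = 1)
  expect_equal(mt2$r, 1)

  expect_error(mantel_test(base[1:3, 1:3], double[1:3, 1:3]), "4 sites")
})

test_that("Mantel r and p agree with the vegan implementation", {
  set.seed(42)
  n <- 8
  a <- as.matrix(stats::dist(matrix(stats::runif(n * 2), n)))
  b <- as.matrix(stats::dist(matrix(stats::runif(n * 2), n)))
  mine <- mantel_test(a, b, n_perm = 999, seed = 7)
  ref <- vegan::mantel(a, b, permutations = 999)
  expect_equal(mine$r, unname(ref$statistic), tolerance = 1e-12)
  # permutation p-values from the two implementations agree closely
  expect_lt(abs(mine$p - ref$signif), 0.05)
})

test_that("distance matrices are symmetric with zero diagonals", {
  cfg <- sim_config(n_pops = 3, n_samples_per_pop = 12, n_snps = 300,
    target_fst = 0.05, seed = 21L)
  gd <- simulate_populations(cfg)
  dm <- distance_matrices(gd)
  for (m in list(dm$genetic, dm$geographic, dm$linearized)) {
    expect_equal(m, t(m))
    expect_true(all(diag(m) == 0))
  }
  expect_identical(rownames(dm$genetic), rownames(dm$geographic))
})
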