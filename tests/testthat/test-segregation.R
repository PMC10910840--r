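test_that("Mendelian offspring distributions are exact", {
  expect_equal(
    unlist(expected_offspring_distribution(1, 1)),
    c(p_homref = 0.25, p_het = 0.5, p_homalt = 0.25,
      expected_alt_freq = 0.5)
  )
  expect_equal(
    unlist(expected_offspring_distribution(0, 1)),
    c(p_homref = 0.5, p_het = 0.5, p_homalt = 0,
      expected_alt_freq = 0.25)
  )
  expect_equal(
    unlist(expected_offspring_distribution(0, 2)),
    c(p_homref = 0, p_het = 1, p_homalt = 0, expected_alt_freq = 0.5)
  )
  expect_error(expected_offspring_distribution(3, 0))
})

test_that("allele-count chi-square matches hand-derived values", {
  exact <- segregation_chisq(50, 200, 0.25)
  expect_equal(exact$statistic, 0)
  expect_equal(exact$p, 1)

  off <- segregation_chisq(60, 200, 0.25)
  expect_equal(off$statistic, 100 / 50 + 100 / 150, tolerance = 1e-12)
  expect_equal(off$p, stats::pchisq(8 / 3, 1, lower.tail = FALSE),
    tolerance = 1e-12)
  expect_equal(round(off$p, 3), 0.102)

  extreme <- segregation_chisq(0, 100, 0.5)
  expect_equal(extreme$statistic, 100)
  expect_lt(extreme$p, 1e-20)

  expect_error(segregation_chisq(1, 10, 0), "strictly")
})

test_that("Fisher combination matches closed forms and handles edges", {
  expect_identical(combine_fisher(0.5), 0.5)
  expect_equal(combine_fisher(c(1, 1)), 1)

  x <- -2 * sum(log(c(0.5, 0.5)))
  expect_equal(combine_fisher(c(0.5, 0.5)), exp(-x / 2) * (1 + x / 2),
    tolerance = 1e-12)
  expect_equal(round(combine_fisher(c(0.5, 0.5)), 4), 0.5966)

  # independent closed forms for df = 4 and df = 6 on random vectors
  set.seed(31)
  for (i in 1:200) {
    p2 <- stats::runif(2)
    x2 <- -2 * sum(log(p2))
    expect_equal(combine_fisher(p2), exp(-x2 / 2) * (1 + x2 / 2),
      tolerance = 1e-10)
    p3 <- stats::runif(3)
    x3 <- -2 * sum(log(p3))
    expect_equal(combine_fisher(p3),
      exp(-x3 / 2) * (1 + x3 / 2 + x3^2 / 8), tolerance = 1e-10)
  }
  expect_warning(res <- combine_fisher(c(0, 0.5)), "clamped")
  expect_gte(res, 0)
})

test_that("Holm adjustment reproduces hand-traced step-downs", {
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(0.5), 0.5)
  expect_equal(holm_adjust(c(0.03, 0.03, 0.03)), c(0.09, 0.09, 0.09))
  # monotone, capped, >= raw
  set.seed(8)
  p <- stats::runif(50)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("only SNPs with a heterozygous parent are tested", {
  fam <- cross_family(
    "f1",
    parent1 = c(0L, 1L, 2L, NA),
    parent2 = c(0L, 0L, 1L, 1L),
    offspring = matrix(c(
      0L, 0L, 0L, 1L,
      0L, 1L, 1L, 1L,
      0L, 0L, 2L, 1L
    ), nrow = 3, byrow = TRUE),
    snp_ids = paste0("v", 1:4)
  )
  res <- run_segregation(list(fam))
  expect_setequal(tidy(res)$snp_id, c("v2", "v3")) # v1 no het, v4 NA parent
})

test_that("a distorted SNP fails after Fisher combination and Holm", {
  set.seed(12)
  n_snps <- 200
  parents <- function() {
    p1 <- rep(1L, n_snps)
    p2 <- sample(0:1, n_snps, replace = TRUE)
    list(p1 = p1, p2 = p2)
  }
  fams <- lapply(1:3, function(i) {
    pr <- parents()
    fam <- simulate_cross(pr$p1, pr$p2, n_offspring = 100, seed = 100 + i,
      family_id = paste0("f", i))
    # SNP 1: replace offspring by hom-ref regardless of expectation
    fam$offspring[, 1] <- 0L
    fam
  })
  res <- run_segregation(fams)
  td <- tidy(res)
  expect_true(td$fail[td$snp_id == "snp00001"])
  # clean SNPs essentially never fail after Holm
  expect_lte(sum(td$fail), 1)
})

test_that("SNPs with no offspring data are excluded, not failed", {
  fam <- cross_family(
    "f1", c(1L, 1L), c(1L, 0L),
    offspring = matrix(c(1L, 0L, NA, NA), nrow = 2),
    snp_ids = c("keep", "empty")
  )
  res <- run_segregation(list(fam))
  expect_identical(tidy(res)$snp_id, "keep")
})

test_that("Mendel-impossible offspring are tallied and still counted", {
  fam <- cross_family(
    "f1", c(0L), c(1L),
    offspring = matrix(c(0L, 1L, 2L, 2L), nrow = 4),
    snp_ids = "v1"
  )
  res <- run_segregation(list(fam))
  td <- tidy(res)
  expect_identical(td$n_inconsistent, 2L)
  # the impossible hom-alts stay in the observed allele counts
  bf <- res$by_family
  expect_identical(bf$total_alleles, 8L)
  expect_identical(bf$observed_alt_count, 5L)
})

test_that("error-free crosses keep the familywise failure rate at bay", {
  set.seed(77)
  n_snps <- 800
  p <- stats::runif(n_snps, 0.2, 0.8)
  fams <- lapply(1:3, function(i) {
    g1 <- stats::rbinom(n_snps, 2, p)
    g2 <- stats::rbinom(n_snps, 2, p)
    simulate_cross(g1, g2, n_offspring = 25, seed = 200 + i,
      family_id = paste0("f", i))
  })
  res <- run_segregation(fams)
  expect_gt(res$n_tested, 300)
  expect_lte(res$failure_fraction, 0.05)
})
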