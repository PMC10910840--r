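test_that("pairwise concordance masks missing calls and is symmetric", {
  expect_equal(pairwise_concordance(c(0, 1, 2, 1), c(0, 1, 2, 1)), 100)
  expect_equal(pairwise_concordance(c(0, 1, 2, 1), c(0, 1, 2, 2)), 75)
  expect_equal(pairwise_concordance(c(0, NA, 2), c(0, 1, 2)), 100)
  expect_true(is.na(pairwise_concordance(c(NA, NA), c(0, 1))))
  set.seed(4)
  a <- sample(c(0:2, NA), 50, replace = TRUE)
  b <- sample(c(0:2, NA), 50, replace = TRUE)
  expect_identical(pairwise_concordance(a, b), pairwise_concordance(b, a))
})

test_that("replicate error rates reproduce the published per-replicate means", {
  t3 <- aealbo_table3()
  reps <- t3[t3$type == "replicate", ]
  errs <- vapply(split(reps$concordance, reps$group),
    replicate_error_rate, numeric(1))
  expect_equal(round(unname(errs), 2), c(0.50, 1.27, 0.43, 0.49))
  expect_equal(replicate_error_rate(100), 0)
})

test_that("mismatch taxonomy classifies allele and zygosity differences", {
  expect_identical(
    classify_mismatch("A", "G", "A", "G", 1L, 2L), "zygosity"
  )
  expect_identical(
    classify_mismatch("A", "G", "T", "G", 0L, 0L), "ref_allele"
  )
  expect_identical(
    classify_mismatch("A", "G", "A", "G", 2L, 2L), character(0)
  )
  # missing call: zygosity not assessed
  expect_identical(
    classify_mismatch("A", "G", "A", "C", NA_integer_, 1L), "alt_allele"
  )
  # categories are independent and can combine
  expect_setequal(
    classify_mismatch("A", "G", "T", "C", 1L, 0L),
    c("ref_allele", "alt_allele", "zygosity")
  )
})

test_that("identical call sets report zero mismatch and empty recurrence", {
  gd <- random_dataset(6, 40, miss_rate = 0.05, seed = 10)
  gd$samples$population <- rep(c("P1", "P2"), each = 3)
  rep_ <- cross_platform_report(gd, gd)
  expect_true(all(rep_$per_sample$pct_zygosity == 0))
  expect_identical(nrow(rep_$recurrence), 0L)
  expect_equal(rep_$overall_mean, 0)
})

test_that("recurrence histogram identities hold on random data", {
  set.seed(15)
  a <- random_dataset(8, 60, miss_rate = 0.1, seed = 31)
  b <- a
  flip <- matrix(runif(length(b$calls)) < 0.1, nrow = 8)
  b$calls[flip & !is.na(b$calls)] <-
    (b$calls[flip & !is.na(b$calls)] + 1L) %% 3L
  a$samples$population <- "P1"
  b$samples$population <- "P1"
  rep_ <- cross_platform_report(a, b)
  n_mismatching_snps <- sum(rep_$per_snp$k > 0)
  expect_identical(sum(rep_$recurrence$n_snps), n_mismatching_snps)
  expect_identical(
    sum(rep_$recurrence$k * rep_$recurrence$n_snps),
    sum(rep_$per_snp$k)
  )
  expect_identical(
    sum(rep_$per_snp$k), sum(rep_$per_sample$n_zygosity_mismatch)
  )
})

test_that("swapped ref/alt polarity is harmonised before comparison", {
  gd <- random_dataset(4, 10, miss_rate = 0, seed = 3)
  flipped <- gd
  flipped$variants$ref <- gd$variants$alt
  flipped$variants$alt <- gd$variants$ref
  flipped$calls <- 2L - gd$calls
  rep_ <- cross_platform_report(gd, flipped)
  expect_identical(rep_$n_polarity_flipped, 10L)
  expect_equal(rep_$overall_mean, 0)
})

test_that("population and overall means are unweighted sample means", {
  gd <- random_dataset(6, 50, miss_rate = 0, seed = 8)
  gd$samples$population <- rep(c("P1", "P2"), c(2, 4))
  noisy <- gd
  noisy$calls[1, 1:10] <- (noisy$calls[1, 1:10] + 1L) %% 3L
  rep_ <- cross_platform_report(gd, noisy)
  expect_equal(rep_$overall_mean, mean(rep_$per_sample$pct_zygosity))
  p1 <- rep_$summary$mean_pct_zygosity[rep_$summary$population == "P1"]
  expect_equal(p1, mean(rep_$per_sample$pct_zygosity[1:2]))
})

test_that("metric filtering drops SNPs below any threshold", {
  gd <- random_dataset(5, 8, miss_rate = 0, seed = 6)
  fld <- c(5.9, rep(10, 7)) # SNP 1 removed by FLD alone
  cr <- c(1, 0.97, rep(1, 6)) # SNP 2 removed by call rate
  depth <- matrix(30L, 5, 8)
  depth[3, 3] <- 19L # SNP 3 removed by per-call depth
  arr <- platform_callset(gd, "array", fld = fld, call_rate = cr)
  sq <- platform_callset(gd, "sequencing", depth = depth)
  filt <- filter_by_metrics(arr, sq)
  expect_setequal(filt$retained, paste0("v", 4:8))
  expect_equal(filt$rate_before, 0)
  expect_equal(filt$rate_after, 0)

  # all metrics passing leaves the universe unchanged
  arr2 <- platform_callset(gd, "array", fld = rep(10, 8),
    call_rate = rep(1, 8))
  sq2 <- platform_callset(gd, "sequencing", depth = matrix(30L, 5, 8))
  expect_setequal(filter_by_metrics(arr2, sq2)$retained, paste0("v", 1:8))
})

test_that("mismatch-metric deciles recover an engineered split", {
  gd <- random_dataset(2, 100, miss_rate = 0, seed = 44)
  other <- gd
  # flip zygosity of the 50 low-metric SNPs for one sample
  low <- 1:50
  other$calls[1, low] <- ifelse(gd$calls[1, low] == 1L, 0L, 1L)
  fld <- c(stats::runif(50, 2, 5), stats::runif(50, 10, 20))
  arr <- platform_callset(gd, "array", fld = fld,
    call_rate = rep(1, 100))
  sq <- platform_callset(other, "sequencing",
    depth = matrix(30L, 2, 100))
  mc <- mismatch_metric_correlation(arr, sq, "fld")
  expect_lt(mc$correlation, 0)
  expect_true(all(mc$by_decile$mismatch_rate[1:5] == 1))
  expect_true(all(mc$by_decile$mismatch_rate[6:10] == 0))

  # a metric independent of mismatches correlates near zero
  set.seed(5)
  arr_r <- platform_callset(gd, "array", fld = stats::runif(100, 2, 20),
    call_rate = rep(1, 100))
  mc0 <- mismatch_metric_correlation(arr_r, sq, "fld")
  expect_lt(abs(mc0$correlation), 0.3)
})
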