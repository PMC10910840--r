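#' Thresholds for the wild-sample quality-control cascade
#'
#' Defaults follow common array-QC practice for population samples: 10%
#' locus missingness, 20% sample missingness, an exact Hardy-Weinberg
#' p-value floor of 1e-5 applied within each population, a 10% MAF floor,
#' a +/-4 SD heterozygosity outlier band, and the KING-robust duplicate
#' cutoff 0.354 (~ 2^-1.5, the midpoint between duplicate and
#' first-degree expectations).
#'
#' @param locus_missing_max,sample_missing_max Missingness ceilings.
#' @param hwe_p_min Per-population exact-test floor.
#' @param maf_min Minor-allele-frequency floor.
#' @param het_sd Heterozygosity outlier band, in standard deviations.
#' @param kinship_max Kinship above which a pair is treated as
#'   duplicate/monozygotic.
#' @return List of class `qc_thresholds`.
#' @export
qc_thresholds <- function(locus_missing_max = 0.10,
                          sample_missing_max = 0.20,
                          hwe_p_min = 1e-5, maf_min = 0.10,
                          het_sd = 4, kinship_max = 0.354) {
  stopifnot(
    locus_missing_max >= 0, locus_missing_max <= 1,
    sample_missing_max >= 0, sample_missing_max <= 1,
    hwe_p_min >= 0, hwe_p_min <= 1, maf_min >= 0, maf_min <= 0.5,
    het_sd > 0, kinship_max > 0
  )
  structure(as.list(environment()), class = "qc_thresholds")
}

#' Exact Hardy-Weinberg test
#'
#' Exact conditional test on the heterozygote count: all heterozygote
#' counts compatible with the observed allele counts are enumerated, each
#' weighted by `n! / (nAA! nAa! naa!) * 2^nAa`, the distribution is
#' normalised, and the p-value is the summed probability of
#' configurations no more probable than the observed one (the standard,
#' not mid-p, convention). Monomorphic loci return 1.
#'
#' @param n_homref,n_het,n_homalt Genotype counts (vectorised).
#' @return Exact p-value(s).
#' @examples
#' hwe_exact_test(1, 0, 1) # 1/3
#' @export
hwe_exact_test <- function(n_homref, n_het, n_homalt) {
  mapply(hwe_exact_one, n_homref, n_het, n_homalt, USE.NAMES = FALSE)
}

hwe_exact_one <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0) abort("no genotyped individuals.")
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  if (n_a == 0 || n_b == 0) return(1)
  n_minor <- min(n_a, n_b)
  h <- seq(n_minor %% 2, n_minor, by = 2) # feasible het counts
  homr <- (n_a - h) / 2
  homa <- (n_b - h) / 2
  logw <- lfactorial(n) - lfactorial(homr) - lfactorial(h) -
    lfactorial(homa) + h * log(2)
  logw <- logw - max(logw)
  prob <- exp(logw) / sum(exp(logw))
  p_obs <- prob[match(n_ab, h)]
  sum(prob[prob <= p_obs * (1 + 1e-12)])
}

#' Flag heterozygosity-outlier samples
#'
#' Per-sample heterozygous-call fraction over non-missing calls; samples
#' deviating more than `het_sd` standard deviations from the mean across
#' samples are flagged. A zero standard deviation flags nothing.
#'
#' @param dataset A [genotype_dataset] with at least 3 samples.
#' @param het_sd Width of the acceptance band in SDs.
#' @return Tibble: `sample_id`, `het_frac`, `z`, `flagged`.
#' @export
individual_heterozygosity_outliers <- function(dataset, het_sd = 4) {
  if (n_samples(dataset) < 3) abort("need at least 3 samples.")
  ss <- sample_stats(dataset)
  mu <- mean(ss$het_frac, na.rm = TRUE)
  sd_ <- stats::sd(ss$het_frac, na.rm = TRUE)
  z <- if (sd_ > 0) (ss$het_frac - mu) / sd_ else rep(0, nrow(ss))
  tibble(
    sample_id = ss$sample_id, het_frac = ss$het_frac, z = z,
    flagged = is.finite(z) & abs(z) > het_sd
  )
}

#' Pairwise KING-robust kinship
#'
#' The between-sample identity-by-state kinship estimator of Manichaikul
#' et al. (2010):
#' `phi = (N_AaAa - 2 * N_AAaa) / (N_Aa(i) + N_Aa(j))`, with all counts
#' taken over loci co-called in the pair. Duplicates give ~0.5,
#' parent-offspring ~0.25, unrelated pairs ~0.
#'
#' @param dataset A [genotype_dataset] with >= 2 samples.
#' @return Tibble: `sample_a`, `sample_b`, `n_cocalled`, `kinship`
#'   (`NA` for pairs with no co-called informative loci).
#' @export
pairwise_kinship <- function(dataset) {
  calls <- dataset$calls
  if (nrow(calls) < 2) abort("need at least 2 samples.")
  m <- !is.na(calls)
  het <- (calls == 1L) & m
  hom0 <- (calls == 0L) & m
  hom2 <- (calls == 2L) & m
  mode(m) <- "numeric"
  mode(het) <- "numeric"
  mode(hom0) <- "numeric"
  mode(hom2) <- "numeric"
  n_hethet <- tcrossprod(het)
  n_opp <- tcrossprod(hom0, hom2) + tcrossprod(hom2, hom0)
  het_i <- tcrossprod(het, m) # het calls of i over loci called in j
  n_co <- tcrossprod(m)
  ids <- dataset$samples$sample_id
  prs <- utils::combn(length(ids), 2)
  i <- prs[1, ]
  j <- prs[2, ]
  denom <- het_i[cbind(i, j)] + het_i[cbind(j, i)]
  phi <- ifelse(denom > 0,
    (n_hethet[cbind(i, j)] - 2 * n_opp[cbind(i, j)]) / denom, NA_real_)
  phi[n_co[cbind(i, j)] == 0] <- NA_real_
  tibble(
    sample_a = ids[i], sample_b = ids[j],
    n_cocalled = as.integer(n_co[cbind(i, j)]), kinship = phi
  )
}

#' Apply the full wild-sample QC cascade
#'
#' Steps in order: (1) loci above `locus_missing_max` missingness;
#' (2) samples above `sample_missing_max`; (3) loci failing the exact
#' Hardy-Weinberg test below `hwe_p_min` in any population; (4) loci
#' below `maf_min`; (5) heterozygosity-outlier samples beyond `het_sd`
#' SDs; (6) of each sample pair above `kinship_max`, the member with the
#' higher missingness. The report records removals per stage; rerunning
#' on the output removes nothing further.
#'
#' @param dataset A [genotype_dataset]; population labels are required
#'   for the HWE step (samples with no label form their own group).
#' @param thresholds A [qc_thresholds()].
#' @return List of class `qc_result`: `data` (filtered dataset), `report`
#'   (tibble `stage`, `n_removed`, `removed_ids`).
#' @export
apply_qc <- function(dataset, thresholds = qc_thresholds()) {
  th <- thresholds
  stages <- list()
  drop_variants <- function(ds, ids, stage) {
    stages[[stage]] <<- ids
    if (length(ids)) {
      ds <- gt_subset(ds, variants = setdiff(ds$variants$id, ids))
    }
    if (n_variants(ds) == 0) {
      abort(paste0("QC stage '", stage, "' removed every locus."))
    }
    ds
  }
  drop_samples <- function(ds, ids, stage) {
    stages[[stage]] <<- ids
    if (length(ids)) {
      ds <- gt_subset(ds, samples = setdiff(ds$samples$sample_id, ids))
    }
    if (n_samples(ds) == 0) {
      abort(paste0("QC stage '", stage, "' removed every sample."))
    }
    ds
  }

  vs <- variant_stats(dataset)
  dataset <- drop_variants(dataset,
    vs$id[vs$missingness > th$locus_missing_max], "locus_missingness")

  ss <- sample_stats(dataset)
  dataset <- drop_samples(dataset,
    ss$sample_id[ss$missingness > th$sample_missing_max],
    "sample_missingness")

  pops <- dataset$samples$population
  pops[is.na(pops)] <- "(none)"
  fail_hwe <- rep(FALSE, n_variants(dataset))
  for (pop in unique(pops)) {
    rows <- which(pops == pop)
    if (length(rows) < 2) next
    sub <- dataset$calls[rows, , drop = FALSE]
    cnt <- cbind(
      colSums(sub == 0L, na.rm = TRUE),
      colSums(sub == 1L, na.rm = TRUE),
      colSums(sub == 2L, na.rm = TRUE)
    )
    called <- rowSums(cnt) > 0
    key <- paste(cnt[, 1], cnt[, 2], cnt[, 3])
    uniq <- !duplicated(key) & called
    pv <- stats::setNames(
      hwe_exact_test(cnt[uniq, 1], cnt[uniq, 2], cnt[uniq, 3]),
      key[uniq]
    )
    p_all <- rep(1, nrow(cnt))
    p_all[called] <- pv[key[called]]
    fail_hwe <- fail_hwe | (p_all < th$hwe_p_min)
  }
  dataset <- drop_variants(dataset, dataset$variants$id[fail_hwe], "hwe")

  vs <- variant_stats(dataset)
  dataset <- drop_variants(dataset,
    vs$id[is.na(vs$maf) | vs$maf < th$maf_min], "maf")

  het <- individual_heterozygosity_outliers(dataset, th$het_sd)
  dataset <- drop_samples(dataset, het$sample_id[het$flagged],
    "heterozygosity")

  kin <- pairwise_kinship(dataset)
  flagged <- kin[!is.na(kin$kinship) & kin$kinship > th$kinship_max, ]
  remove_kin <- character(0)
  if (nrow(flagged) > 0) {
    ss <- sample_stats(dataset)
    miss <- stats::setNames(ss$missingness, ss$sample_id)
    for (r in seq_len(nrow(flagged))) {
      a <- flagged$sample_a[r]
      b <- flagged$sample_b[r]
      if (a %in% remove_kin || b %in% remove_kin) next
      remove_kin <- c(remove_kin, if (miss[[a]] >= miss[[b]]) a else b)
    }
  }
  dataset <- drop_samples(dataset, remove_kin, "kinship")

  structure(
    list(
      data = dataset,
      report = tibble(
        stage = names(stages),
        n_removed = lengths(stages),
        removed_ids = unname(purrr::map(stages, identity))
      )
    ),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result>\n")
  print(select(x$report, "stage", "n_removed"))
  cat(
    "  retained:", n_samples(x$data), "samples x", n_variants(x$data),
    "SNPs\n"
  )
  invisible(x)
}

#' @export
glance.qc_result <- function(x, ...) {
  tibble(
    n_samples = n_samples(x$data), n_variants = n_variants(x$data),
    n_removed_total = sum(x$report$n_removed)
  )
}
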