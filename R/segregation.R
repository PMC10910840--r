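#' A laboratory cross family
#'
#' Two parental genotype vectors plus the offspring genotype matrix for one
#' single-pair mating, all over the same SNP universe.
#'
#' @param family_id Family label.
#' @param parent1,parent2 Integer genotype vectors in `{0, 1, 2, NA}`.
#' @param offspring Integer matrix, offspring in rows, SNPs in columns.
#' @param snp_ids SNP identifiers (length = number of SNPs).
#' @return An object of class `cross_family`.
#' @export
cross_family <- function(family_id, parent1, parent2, offspring,
                         snp_ids = NULL) {
  offspring <- as.matrix(offspring)
  storage.mode(offspring) <- "integer"
  L <- length(parent1)
  if (length(parent2) != L || ncol(offspring) != L) {
    abort("parental and offspring SNP dimensions must agree.")
  }
  ids <- snp_ids %||% colnames(offspring) %||% sprintf("snp%05d", seq_len(L))
  colnames(offspring) <- ids
  structure(
    list(
      family_id = family_id, parent1 = as.integer(parent1),
      parent2 = as.integer(parent2), offspring = offspring, snp_ids = ids
    ),
    class = "cross_family"
  )
}

#' @export
print.cross_family <- function(x, ...) {
  cat(
    "<cross_family>", x$family_id, "-", nrow(x$offspring), "offspring x",
    length(x$snp_ids), "SNPs\n"
  )
  invisible(x)
}

#' Build cross families from a genotype dataset and a pedigree
#'
#' @param dataset A [genotype_dataset] containing parents and offspring.
#' @param pedigree Tibble as returned by [read_pedigree()]: columns
#'   `family_id`, `sample_id`, `role`.
#' @return List of [cross_family()] objects, one per family.
#' @export
cross_families <- function(dataset, pedigree) {
  split(pedigree, pedigree$family_id) |>
    purrr::map(function(fam) {
      p1 <- fam$sample_id[fam$role == "parent1"]
      p2 <- fam$sample_id[fam$role == "parent2"]
      off <- fam$sample_id[fam$role == "offspring"]
      if (length(p1) != 1 || length(p2) != 1) {
        abort(paste0("family ", fam$family_id[1],
          " must have exactly one parent1 and one parent2."))
      }
      i <- match(c(p1, p2, off), dataset$samples$sample_id)
      if (anyNA(i)) abort("pedigree sample missing from dataset.")
      cross_family(
        fam$family_id[1],
        dataset$calls[i[1], ], dataset$calls[i[2], ],
        dataset$calls[i[-(1:2)], , drop = FALSE],
        snp_ids = dataset$variants$id
      )
    })
}

#' Mendelian offspring genotype distribution for a parental pair
#'
#' Exact distribution of offspring dosages for unlinked biallelic loci:
#' each parent transmits its alleles with equal probability. The expected
#' offspring alternative-allele frequency is `(g1 + g2) / 4`.
#'
#' @param g1,g2 Parental dosages in `{0, 1, 2}`.
#' @return Tibble with columns `p_homref`, `p_het`, `p_homalt`,
#'   `expected_alt_freq` (vectorised over parental pairs).
#' @examples
#' expected_offspring_distribution(1, 1) # 1/4, 1/2, 1/4
#' @export
expected_offspring_distribution <- function(g1, g2) {
  stopifnot(all(g1 %in% 0:2), all(g2 %in% 0:2))
  p_alt1 <- g1 / 2
  p_alt2 <- g2 / 2
  p_homalt <- p_alt1 * p_alt2
  p_homref <- (1 - p_alt1) * (1 - p_alt2)
  tibble(
    p_homref = p_homref,
    p_het = 1 - p_homref - p_homalt,
    p_homalt = p_homalt,
    expected_alt_freq = (g1 + g2) / 4
  )
}

#' Allele-count chi-square test against a Mendelian expectation
#'
#' Two-cell goodness-of-fit on offspring allele counts against the
#' expected alternative-allele frequency, 1 degree of freedom, upper-tail
#' p-value.
#'
#' @param observed_alt_count Observed alternative alleles among offspring.
#' @param total_alleles Total non-missing offspring alleles.
#' @param expected_alt_freq Mendelian expectation in `(0, 1)`.
#' @return Tibble with `statistic` and `p` (vectorised).
#' @examples
#' segregation_chisq(60, 200, 0.25) # X2 = 2.667, p ~ 0.102
#' @export
segregation_chisq <- function(observed_alt_count, total_alleles,
                              expected_alt_freq) {
  stopifnot(all(total_alleles > 0))
  if (any(expected_alt_freq <= 0 | expected_alt_freq >= 1)) {
    abort(paste0("expected_alt_freq must lie strictly in (0, 1); fixed ",
      "expectations are screened as Mendelian inconsistencies instead."))
  }
  e_alt <- total_alleles * expected_alt_freq
  e_ref <- total_alleles - e_alt
  o_alt <- observed_alt_count
  o_ref <- total_alleles - o_alt
  stat <- (o_alt - e_alt)^2 / e_alt + (o_ref - e_ref)^2 / e_ref
  tibble(statistic = stat, p = stats::pchisq(stat, df = 1,
    lower.tail = FALSE))
}

#' Fisher combination of independent p-values
#'
#' `X = -2 * sum(log(p))` referred to the upper tail of a chi-square with
#' `2k` degrees of freedom. A single p-value is returned unchanged; zero
#' p-values are clamped to the smallest positive double with a warning.
#'
#' @param p_values Numeric vector of p-values in `(0, 1]`.
#' @return Combined p-value.
#' @export
combine_fisher <- function(p_values) {
  p <- p_values[!is.na(p_values)]
  if (length(p) == 0) return(NA_real_)
  if (any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  if (any(p == 0)) {
    warn("zero p-value clamped before Fisher combination.")
    p[p == 0] <- .Machine$double.xmin
  }
  if (length(p) == 1) return(p)
  x <- -2 * sum(log(p))
  stats::pchisq(x, df = 2 * length(p), lower.tail = FALSE)
}

#' Holm step-down adjustment
#'
#' Familywise-error-controlling step-down correction (Holm 1979), returned
#' in the original order.
#'
#' @param p_values Numeric vector of p-values.
#' @return Adjusted p-values.
#' @export
holm_adjust <- function(p_values) {
  stats::p.adjust(p_values, method = "holm")
}

#' Run the Mendelian segregation test across crosses
#'
#' Per family, only SNPs with at least one heterozygous (and no missing)
#' parent are testable; offspring alleles are counted over non-missing
#' calls and a two-cell chi-square compares the observed
#' alternative-allele count with the Mendelian expectation.
#' Mendel-impossible offspring genotypes (those with expected probability
#' zero under the parental pair) are additionally tallied per SNP as a
#' separate inconsistency count; their alleles remain in the observed
#' counts, since the test compares predicted and observed allele
#' frequencies over all offspring.
#' P-values of SNPs tested in several families are combined with Fisher's
#' method, the combined values are Holm-adjusted over all tested SNPs, and
#' a SNP fails when its adjusted p falls below `alpha`.
#'
#' @param families List of [cross_family()] objects.
#' @param alpha Familywise significance level (default 0.05).
#' @param cells `"allele"` (default, 2-cell allele-count test) or
#'   `"genotype"` (3-cell genotype-count test).
#' @return Object of class `segregation_result`: `by_snp` tibble (one row
#'   per tested SNP: combined, adjusted p, failure flag, Mendelian
#'   inconsistency count), `by_family` tibble of per-family tests, and the
#'   overall `failure_fraction`. [generics::tidy()] returns `by_snp`,
#'   [generics::glance()] a one-row summary.
#' @export
run_segregation <- function(families, alpha = 0.05,
                            cells = c("allele", "genotype")) {
  cells <- match.arg(cells)
  if (length(families) == 0) abort("need at least one family.")
  per_family <- purrr::map(families, function(fam) {
    g1 <- fam$parent1
    g2 <- fam$parent2
    testable <- !is.na(g1) & !is.na(g2) & (g1 == 1 | g2 == 1)
    idx <- which(testable)
    if (length(idx) == 0) return(NULL)
    off <- fam$offspring[, idx, drop = FALSE]
    exp_d <- expected_offspring_distribution(g1[idx], g2[idx])
    probs <- rbind(exp_d$p_homref, exp_d$p_het, exp_d$p_homalt)
    # Mendel-impossible calls (observed state with expected probability
    # zero) are tallied for reporting; their alleles still enter the
    # observed counts, since the test compares observed and predicted
    # allele frequencies over all offspring
    imp <- matrix(FALSE, nrow = nrow(off), ncol = ncol(off))
    ok <- !is.na(off)
    imp[ok] <- probs[cbind(
      off[ok] + 1L,
      rep(seq_len(ncol(off)), each = nrow(off))[ok]
    )] == 0
    n_called <- colSums(ok)
    obs_alt <- colSums(off, na.rm = TRUE)
    res <- tibble(
      family_id = fam$family_id,
      snp_id = fam$snp_ids[idx],
      g1 = g1[idx], g2 = g2[idx],
      expected_alt_freq = exp_d$expected_alt_freq,
      n_offspring_called = as.integer(n_called),
      observed_alt_count = as.integer(obs_alt),
      total_alleles = 2L * as.integer(n_called),
      n_inconsistent = as.integer(colSums(imp))
    )
    has_data <- res$total_alleles > 0
    res$statistic <- NA_real_
    res$p <- NA_real_
    if (any(has_data)) {
      if (cells == "allele") {
        ct <- segregation_chisq(
          res$observed_alt_count[has_data], res$total_alleles[has_data],
          res$expected_alt_freq[has_data]
        )
        res$statistic[has_data] <- ct$statistic
        res$p[has_data] <- ct$p
      } else {
        hd <- which(has_data)
        obs3 <- sapply(hd, function(j) {
          tabulate(off[, j] + 1L, nbins = 3)
        })
        for (m in seq_along(hd)) {
          j <- hd[m]
          pr <- probs[, j]
          keep <- pr > 0
          e <- res$n_offspring_called[j] * pr[keep]
          o <- obs3[keep, m]
          stat <- sum((o - e)^2 / e)
          res$statistic[j] <- stat
          res$p[j] <- stats::pchisq(stat, df = sum(keep) - 1,
            lower.tail = FALSE)
        }
      }
    }
    res
  })
  by_family <- bind_rows(per_family)
  if (nrow(by_family) == 0) abort("no testable SNP in any family.")
  by_snp <- by_family |>
    filter(!is.na(.data$p)) |>
    group_by(.data$snp_id) |>
    summarise(
      n_families = n(),
      p_combined = combine_fisher(.data$p),
      n_inconsistent = sum(.data$n_inconsistent),
      .groups = "drop"
    )
  by_snp$p_adjusted <- holm_adjust(by_snp$p_combined)
  by_snp$fail <- by_snp$p_adjusted < alpha
  structure(
    list(
      by_snp = by_snp, by_family = by_family, alpha = alpha,
      n_tested = nrow(by_snp), n_failed = sum(by_snp$fail),
      failure_fraction = mean(by_snp$fail)
    ),
    class = "segregation_result"
  )
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(
    "<segregation_result>", x$n_tested, "SNPs tested,", x$n_failed,
    sprintf("failed (%.2f%%) at alpha = %g\n", 100 * x$failure_fraction,
      x$alpha)
  )
  invisible(x)
}

#' @export
tidy.segregation_result <- function(x, ...) x$by_snp

#' @export
glance.segregation_result <- function(x, ...) {
  tibble(
    n_tested = x$n_tested, n_failed = x$n_failed,
    failure_fraction = x$failure_fraction,
    pct_failed = 100 * x$failure_fraction, alpha = x$alpha
  )
}
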