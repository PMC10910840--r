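#' Configuration for the synthetic-data generator
#'
#' Collects every tunable of the simulator with defaults mirroring the
#' validation study's conditions: five ancestral population clusters at
#' moderate differentiation, single-pair laboratory crosses of ~25
#' offspring, a low-coverage sequencing arm (so a meaningful share of
#' calls sits below the depth-20 stratum) and an array arm with a
#' per-call error rate in the sub-percent range seen for technical
#' replicates.
#'
#' @param n_pops Number of populations.
#' @param n_samples_per_pop Diploid samples per population.
#' @param n_snps Number of biallelic SNPs.
#' @param target_fst Balding–Nichols differentiation parameter, in `[0, 1)`.
#' @param ancestral_maf_range Range the ancestral alt-allele frequency is
#'   drawn from (uniform).
#' @param n_offspring Offspring per simulated cross.
#' @param genotyping_error_rate Per-call probability an offspring call is
#'   replaced by a uniform draw from the other two genotype states.
#' @param mean_depth Mean sequencing read depth per call.
#' @param depth_dispersion Negative-binomial overdispersion of depth;
#'   `0` gives Poisson depths.
#' @param array_error_rate Baseline per-call array miscall probability.
#' @param low_fld_frac Fraction of array SNPs drawn with a poor Fisher
#'   linear discriminant (FLD below 6); these probes also carry an
#'   error rate inflated by `low_fld_error_boost`.
#' @param low_fld_error_boost Multiplier on `array_error_rate` for
#'   low-FLD probes.
#' @param call_rate_shape1,call_rate_shape2 Beta parameters for the
#'   per-SNP array call rate used to mask calls.
#' @param seed Integer seed; every generator is bit-reproducible under it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 5, n_samples_per_pop = 20, n_snps = 5000,
                       target_fst = 0.10,
                       ancestral_maf_range = c(0.05, 0.5),
                       n_offspring = 25, genotyping_error_rate = 0,
                       mean_depth = 25, depth_dispersion = 0.3,
                       array_error_rate = 0.005,
                       low_fld_frac = 0.10, low_fld_error_boost = 10,
                       call_rate_shape1 = 199, call_rate_shape2 = 1,
                       seed = 1L) {
  cfg <- as.list(environment())
  rates <- c(
    target_fst, genotyping_error_rate, array_error_rate, low_fld_frac
  )
  if (any(rates < 0 | rates > 1) || target_fst >= 1) {
    abort("rates must lie in [0, 1] and target_fst in [0, 1).")
  }
  if (mean_depth <= 0) abort("mean_depth must be positive.")
  if (is.null(seed)) abort("a seed is mandatory.")
  if (any(ancestral_maf_range <= 0) || any(ancestral_maf_range >= 1) ||
    diff(ancestral_maf_range) < 0) {
    abort("ancestral_maf_range must be increasing within (0, 1).")
  }
  structure(cfg, class = "sim_config")
}

# WGS-like category mix (intron/intergenic/synonymous/non-synonymous/
# 5'UTR/3'UTR), close to what shotgun discovery yields in this genome.
sim_category_probs <- c(
  intron = 0.4481, intergenic = 0.3475, synonymous = 0.1345,
  non_synonymous = 0.0235, utr5 = 0.0237, utr3 = 0.0227
)

sim_variant_table <- function(n_snps) {
  chrom_len <- c(`1` = 360e6, `2` = 480e6, `3` = 410e6)
  chrom <- sample(names(chrom_len), n_snps, replace = TRUE,
    prob = chrom_len / sum(chrom_len))
  pos <- vapply(chrom, function(ch) {
    sample.int(chrom_len[[ch]], 1L)
  }, integer(1))
  ord <- order(chrom, pos)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  tibble(
    id = sprintf("snp%05d", seq_len(n_snps)),
    chrom = chrom[ord], pos = pos[ord], ref = ref, alt = alt,
    category = sample(names(sim_category_probs), n_snps, replace = TRUE,
      prob = sim_category_probs),
    score = stats::runif(n_snps)
  )
}

#' Simulate structured multi-population genotypes
#'
#' Per SNP an ancestral alt-allele frequency `p` is drawn uniformly on
#' `ancestral_maf_range`; each population's frequency is then drawn from
#' the Balding–Nichols distribution
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` with `F = target_fst`
#' (for `F = 0` all populations share `p` exactly), and genotypes are
#' binomial draws of two alleles. Populations are also assigned
#' synthetic sampling coordinates so distance-based analyses can run.
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_dataset] with population labels and coordinates.
#' @export
simulate_populations <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_pop <- cfg$n_pops
  n_per <- cfg$n_samples_per_pop
  L <- cfg$n_snps
  p_anc <- stats::runif(L, cfg$ancestral_maf_range[1],
    cfg$ancestral_maf_range[2])
  f <- cfg$target_fst
  freqs <- matrix(NA_real_, nrow = n_pop, ncol = L)
  for (k in seq_len(n_pop)) {
    freqs[k, ] <- if (f == 0) {
      p_anc
    } else {
      stats::rbeta(L, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    }
  }
  calls <- matrix(NA_integer_, nrow = n_pop * n_per, ncol = L)
  for (k in seq_len(n_pop)) {
    rows <- (k - 1) * n_per + seq_len(n_per)
    calls[rows, ] <- stats::rbinom(n_per * L, 2, rep(freqs[k, ],
      each = n_per))
  }
  pops <- paste0("pop", seq_len(n_pop))
  site_lat <- stats::runif(n_pop, -10, 45)
  site_lon <- stats::runif(n_pop, 75, 145)
  samples <- tibble(
    sample_id = sprintf("%s_s%02d", rep(pops, each = n_per),
      rep(seq_len(n_per), n_pop)),
    population = rep(pops, each = n_per),
    lat = rep(site_lat, each = n_per),
    lon = rep(site_lon, each = n_per)
  )
  genotype_dataset(calls, sim_variant_table(L), samples)
}

#' Simulate a single-pair mating
#'
#' Offspring genotypes are drawn per SNP from the exact Mendelian
#' distribution implied by the parental genotypes (see
#' [expected_offspring_distribution()]); each call is then, with
#' probability `error_rate`, replaced by a uniform draw from the other
#' two genotype states. A missing parental call yields missing offspring
#' calls at that SNP.
#'
#' @param parent1,parent2 Integer genotype vectors in `{0, 1, 2, NA}`.
#' @param n_offspring Number of offspring.
#' @param error_rate Per-call perturbation probability.
#' @param seed Optional integer seed.
#' @param family_id Label for the family.
#' @param snp_ids Optional SNP ids (defaults to `snp1..L`).
#' @return A `cross_family` object (see [cross_family()]).
#' @export
simulate_cross <- function(parent1, parent2, n_offspring = 25,
                           error_rate = 0, seed = NULL,
                           family_id = "fam1", snp_ids = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(parent1) == length(parent2), error_rate >= 0,
    error_rate <= 1)
  L <- length(parent1)
  gamete <- function(g, n) {
    # allele transmitted by a parent of dosage g, n draws per SNP
    out <- matrix(NA_integer_, nrow = n, ncol = L)
    known <- which(!is.na(g))
    if (length(known)) {
      out[, known] <- stats::rbinom(n * length(known), 1,
        rep(g[known] / 2, each = n))
    }
    out
  }
  off <- gamete(as.integer(parent1), n_offspring) +
    gamete(as.integer(parent2), n_offspring)
  if (error_rate > 0) {
    hit <- matrix(stats::runif(length(off)) < error_rate, nrow = n_offspring)
    hit[is.na(off)] <- FALSE
    if (any(hit)) {
      cur <- off[hit]
      pick <- stats::runif(sum(hit)) < 0.5
      # uniform over the two states other than the current one
      other1 <- c(1L, 0L, 0L)[cur + 1L]
      other2 <- c(2L, 2L, 1L)[cur + 1L]
      off[hit] <- ifelse(pick, other1, other2)
    }
  }
  ids <- snp_ids %||% sprintf("snp%05d", seq_len(L))
  cross_family(family_id, as.integer(parent1), as.integer(parent2), off,
    snp_ids = ids)
}

#' Simulate paired array and sequencing call sets from a truth set
#'
#' The array arm flips each true call with a per-SNP error rate (uniform
#' draw from the other two states), draws a per-SNP FLD score with a
#' configurable fraction of poorly separating probes (FLD < 6, with
#' error rate inflated by `low_fld_error_boost`), and masks calls to a
#' Beta-drawn per-SNP call rate. The sequencing arm draws a per-call
#' depth `d` (negative binomial around `mean_depth`, Poisson when
#' `depth_dispersion = 0`); homozygotes are always read correctly, while
#' a heterozygote is called heterozygous only if both alleles are seen
#' among the `d` reads (miscall probability `(1/2)^(d-1)`); `d = 0`
#' yields a missing call. This reproduces the depth-dependent
#' heterozygote-miscall mechanism that dominates chip-vs-WGS mismatches.
#'
#' @param truth A complete [genotype_dataset] of true genotypes.
#' @param cfg A [sim_config()]; the platform parameters are used.
#' @param seed Optional seed overriding `cfg$seed`.
#' @return List with elements `array` and `sequencing`, both
#'   [platform_callset]s.
#' @export
simulate_platform_pair <- function(truth, cfg = sim_config(), seed = NULL) {
  stopifnot(inherits(truth, "genotype_dataset"))
  if (cfg$mean_depth <= 0) abort("mean_depth must be positive.")
  set.seed(seed %||% cfg$seed)
  calls <- truth$calls
  n <- nrow(calls)
  L <- ncol(calls)

  # --- array arm
  low_fld <- stats::runif(L) < cfg$low_fld_frac
  fld <- ifelse(low_fld, stats::runif(L, 2, 6), stats::runif(L, 6, 20))
  err_snp <- ifelse(low_fld,
    pmin(1, cfg$array_error_rate * cfg$low_fld_error_boost),
    cfg$array_error_rate)
  arr <- calls
  hit <- matrix(stats::runif(n * L) < rep(err_snp, each = n), nrow = n)
  hit[is.na(arr)] <- FALSE
  if (any(hit)) {
    cur <- arr[hit]
    pick <- stats::runif(sum(hit)) < 0.5
    arr[hit] <- ifelse(pick, c(1L, 0L, 0L)[cur + 1L], c(2L, 2L, 1L)[cur + 1L])
  }
  cr <- stats::rbeta(L, cfg$call_rate_shape1, cfg$call_rate_shape2)
  mask <- matrix(stats::runif(n * L) >= rep(cr, each = n), nrow = n)
  arr[mask] <- NA_integer_
  realized_cr <- colMeans(!is.na(arr))
  array_ds <- truth
  array_ds$calls <- arr
  array_set <- platform_callset(array_ds, "array", fld = fld,
    call_rate = realized_cr)

  # --- sequencing arm
  if (cfg$depth_dispersion > 0) {
    size <- 1 / cfg$depth_dispersion
    depth <- matrix(stats::rnbinom(n * L, size = size, mu = cfg$mean_depth),
      nrow = n)
  } else {
    depth <- matrix(stats::rpois(n * L, cfg$mean_depth), nrow = n)
  }
  seqc <- calls
  het <- !is.na(calls) & calls == 1L & depth > 0
  if (any(het)) {
    k_alt <- stats::rbinom(sum(het), depth[het], 0.5)
    seqc[het] <- ifelse(k_alt == 0, 0L,
      ifelse(k_alt == depth[het], 2L, 1L))
  }
  seqc[depth == 0] <- NA_integer_
  seq_ds <- truth
  seq_ds$calls <- seqc
  seq_set <- platform_callset(seq_ds, "sequencing", depth = depth)

  list(array = array_set, sequencing = seq_set)
}
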