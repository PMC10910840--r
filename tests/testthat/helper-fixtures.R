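# Shared fixtures and independent oracles used across the suite.

make_toy_dataset <- function(calls, categories = NULL, pops = NULL,
                             pos = NULL, chrom = NULL) {
  calls <- as.matrix(calls)
  L <- ncol(calls)
  variants <- tibble::tibble(
    id = paste0("v", seq_len(L)),
    chrom = chrom %||% rep("1", L),
    pos = pos %||% as.integer(seq_len(L) * 1000),
    ref = rep("A", L),
    alt = rep("G", L),
    category = categories %||% rep("unknown", L)
  )
  samples <- tibble::tibble(
    sample_id = paste0("s", seq_len(nrow(calls))),
    population = pops %||% rep(NA_character_, nrow(calls))
  )
  genotype_dataset(calls, variants, samples)
}

random_dataset <- function(n_samples, n_snps, miss_rate = 0.1, seed = 42) {
  set.seed(seed)
  calls <- matrix(
    sample(c(0:2, NA), n_samples * n_snps, replace = TRUE,
      prob = c((1 - miss_rate) * c(0.4, 0.4, 0.2), miss_rate)),
    nrow = n_samples
  )
  make_toy_dataset(calls)
}

# Sequential allele-pairing oracle for the exact HWE test: individuals
# draw two alleles without replacement from the allele pool; the DP
# tracks (remaining A alleles, heterozygotes so far). Independent of the
# multinomial-weight formula used by the implementation.
hwe_het_distribution_oracle <- function(n, n_a) {
  # state matrix P[a + 1, h + 1]: a = remaining A alleles, h = hets so far
  p <- matrix(0, nrow = n_a + 1, ncol = n + 1)
  p[n_a + 1, 1] <- 1
  for (ind in seq_len(n)) {
    q <- matrix(0, nrow = n_a + 1, ncol = n + 1)
    left <- 2 * (n - ind + 1) # alleles in the pool before this draw
    tot <- left * (left - 1)
    for (a in 0:min(n_a, left)) {
      rowp <- p[a + 1, ]
      if (all(rowp == 0)) next
      b <- left - a
      if (a >= 2) { # hom A: a drops by 2
        q[a - 1, ] <- q[a - 1, ] + rowp * a * (a - 1) / tot
      }
      if (b >= 2) { # hom B: a unchanged
        q[a + 1, ] <- q[a + 1, ] + rowp * b * (b - 1) / tot
      }
      if (a >= 1 && b >= 1) { # het: a drops by 1, h grows by 1
        shifted <- c(0, rowp[-(n + 1)])
        q[a, ] <- q[a, ] + shifted * 2 * a * b / tot
      }
    }
    p <- q
  }
  stats::setNames(p[1, ], 0:n)
}

hwe_exact_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_minor <- min(n_a, 2 * n - n_a)
  if (n_minor == 0) return(1)
  dist <- hwe_het_distribution_oracle(n, n_minor)
  probs <- dist[dist > 0]
  p_obs <- dist[[as.character(n_ab)]]
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# Independent Weir & Cockerham (1984) component oracle, written directly
# from the published component equations for r populations at one locus.
wc_oracle_one_locus <- function(counts) {
  # counts: matrix pops x 3 of genotype counts (homref, het, homalt)
  n_i <- rowSums(counts)
  keep <- n_i > 0
  counts <- counts[keep, , drop = FALSE]
  n_i <- n_i[keep]
  r <- nrow(counts)
  p_i <- (2 * counts[, 3] + counts[, 2]) / (2 * n_i)
  h_i <- counts[, 2] / n_i
  nbar <- sum(n_i) / r
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
    (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# Markov-haplotype panel with exponentially decaying allele correlation:
# cor(dosage_i, dosage_j) ~ exp(-d / decay_bp), hence r^2 ~ exp(-2d / decay).
correlated_genotype_panel <- function(n_samples, positions, decay_bp,
                                      seed = 1) {
  set.seed(seed)
  L <- length(positions)
  hap <- function() {
    h <- matrix(0L, nrow = n_samples, ncol = L)
    h[, 1] <- stats::rbinom(n_samples, 1, 0.5)
    for (j in 2:L) {
      rho <- exp(-(positions[j] - positions[j - 1]) / decay_bp)
      keep <- stats::rbinom(n_samples, 1, rho)
      h[, j] <- ifelse(keep == 1, h[, j - 1],
        stats::rbinom(n_samples, 1, 0.5))
    }
    h
  }
  calls <- hap() + hap()
  make_toy_dataset(calls, pos = as.integer(positions))
}
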