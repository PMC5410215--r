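# Shared fixture builders and independent oracles for the test suite.

# Receptor mixtures with almost every sample triple negative, so cohorts of a
# target TNBC size can be generated directly.
mostly_tnbc_mixture <- function(positive_fraction = 0.1, separation = 4.5) {
  make <- function(mu_neg) c(mu_neg = mu_neg, sd_neg = 1,
                             mu_pos = mu_neg + separation, sd_pos = 1,
                             positive_fraction = positive_fraction)
  list(ER = make(6), PR = make(5.5), HER2 = make(7))
}

# The planted-structure cohort used by the clustering / signature stages:
# 5 subtypes, 10 markers each, effect 2, noise 0.5 (210 samples, ~150 TNBC).
planted_cohort <- function(seed, n_subtypes = 5, samples_per_dataset = 70,
                           noise_sd = 0.5, marker_effect = 2,
                           batch_shift_sd = 0.5, n_probes = 300) {
  generate_cohort(sim_config(
    n_datasets = 3, samples_per_dataset = samples_per_dataset,
    n_probes = n_probes, receptor_mixture = mostly_tnbc_mixture(),
    n_subtypes = n_subtypes, markers_per_subtype = 10,
    marker_effect = marker_effect, noise_sd = noise_sd,
    batch_shift_sd = batch_shift_sd, seed = seed
  ))
}

tnbc_submatrix <- function(cohort, normalized = NULL) {
  truth <- cohort$truth$samples
  tn <- truth$sample_id[truth$tnbc]
  x <- if (is.null(normalized)) cohort$expr else normalized
  expr_table(expr_values(x)[, tn, drop = FALSE], batch = expr_batch(x)[tn])
}

truth_labels_for <- function(cohort, ids) {
  truth <- cohort$truth$samples
  truth$subtype[match(ids, truth$sample_id)]
}

# Independent quantile-normalization oracle: sort each column, average
# rank-wise, reassign by rank (tie-free inputs only).
qn_oracle <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(col) ref[rank(col)])
  dimnames(out) <- dimnames(m)
  out
}

# Independent maximum-likelihood oracle for the two-component mixture: dense
# grid over the two means, with weights and variances profiled at each grid
# point by fixed-mean EM steps.
grid_mle_oracle <- function(x, mu1_grid, mu2_grid, profile_iters = 15) {
  best <- list(loglik = -Inf)
  for (m1 in mu1_grid) {
    for (m2 in mu2_grid) {
      w <- c(0.5, 0.5)
      v <- c(stats::var(x), stats::var(x)) / 2
      ll <- -Inf
      for (it in seq_len(profile_iters)) {
        d1 <- w[1] * stats::dnorm(x, m1, sqrt(v[1]))
        d2 <- w[2] * stats::dnorm(x, m2, sqrt(v[2]))
        tot <- d1 + d2
        r2 <- d2 / tot
        r1 <- 1 - r2
        n1 <- max(sum(r1), 1e-8); n2 <- max(sum(r2), 1e-8)
        v <- c(max(sum(r1 * (x - m1)^2) / n1, 1e-4),
               max(sum(r2 * (x - m2)^2) / n2, 1e-4))
        w <- c(n1, n2) / length(x)
        ll <- sum(log(tot))
      }
      if (ll > best$loglik) best <- list(mu = c(m1, m2), loglik = ll)
    }
  }
  best
}
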