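block_expr <- function(n_per = 6, centers = c(0, 10), seed = 1) {
  # duplicated points in well-separated groups
  m <- withr::with_seed(seed, {
    vals <- lapply(centers, function(c0) matrix(c0, nrow = 4, ncol = n_per))
    do.call(cbind, vals)
  })
  dimnames(m) <- list(sprintf("p%d", 1:4),
                      sprintf("s%02d", seq_len(ncol(m))))
  expr_table(m)
}

test_that("separable duplicate groups give a 0/1 consensus matrix", {
  x <- block_expr()
  cm <- consensus_matrix(x, k = 2, n_resamples = 50, subsample_fraction = 0.8,
                         seed = 3)
  grp <- rep(1:2, each = 6)
  within <- cm$M[outer(grp, grp, "==") & upper.tri(cm$M)]
  between <- cm$M[outer(grp, grp, "!=") & upper.tri(cm$M)]
  included <- cm$I[upper.tri(cm$I)] > 0
  expect_true(all(within[cm$I[outer(grp, grp, "==") & upper.tri(cm$M)] > 0] == 1))
  expect_true(all(between == 0))
  # consensus entries are valid ratios
  expect_true(all(cm$M >= 0 & cm$M <= 1))
  expect_true(all(cm$M * cm$I <= cm$I))
  expect_true(all(diag(cm$M)[diag(cm$I) > 0] == 1))
})

test_that("with subsample fraction 1 and a stable clusterer, M is the co-membership indicator", {
  x <- block_expr()
  cm1 <- consensus_matrix(x, k = 2, n_resamples = 1, subsample_fraction = 1,
                          seed = 5)
  cm50 <- consensus_matrix(x, k = 2, n_resamples = 50, subsample_fraction = 1,
                           seed = 6)
  expect_true(all(cm50$M %in% c(0, 1)))
  expect_identical(cm50$M, cm1$M)
  expect_error(consensus_matrix(x, k = 40, n_resamples = 5), "exceeds")
  expect_error(consensus_matrix(x, k = 1, n_resamples = 5), "at least 2")
})

test_that("consensus runs are deterministic given the seed", {
  co <- planted_cohort(seed = 2, n_subtypes = 3, samples_per_dataset = 20,
                       n_probes = 60)
  x <- tnbc_submatrix(co)
  a <- consensus_matrix(x, k = 3, n_resamples = 30, seed = 7)
  b <- consensus_matrix(x, k = 3, n_resamples = 30, seed = 7)
  expect_identical(a$M, b$M)
})

test_that("CDF area has its closed-form values on degenerate and uniform input", {
  x <- block_expr()
  mk_cm <- function(M) {
    structure(list(M = M, I = matrix(50, nrow(M), ncol(M)),
                   sample_ids = rownames(M), k = 2, params = list()),
              class = "tnbc_consensus_matrix")
  }
  n <- 12
  ids <- sprintf("s%02d", 1:n)
  zero <- matrix(0, n, n, dimnames = list(ids, ids)); diag(zero) <- 1
  expect_equal(cdf_and_area(mk_cm(zero))$area, 1)

  # half zeros, half ones -> area 0.5
  half <- zero
  half[1:6, 1:6] <- 1
  v <- half[upper.tri(half)]
  expect_equal(cdf_and_area(mk_cm(half))$area, mean(v == 0))

  # uniform entries -> area ~ 0.5
  u <- matrix(0, 150, 150)
  u[upper.tri(u)] <- withr::with_seed(4, runif(sum(upper.tri(u))))
  u <- u + t(u); diag(u) <- 1
  dimnames(u) <- list(sprintf("u%03d", 1:150), sprintf("u%03d", 1:150))
  expect_lt(abs(cdf_and_area(mk_cm(u))$area - 0.5), 0.02)
})

test_that("delta areas follow the proportional-increase recurrence", {
  d <- delta_areas(c(`2` = 0.4, `3` = 0.6))
  expect_equal(d$delta, c(0.4, 0.5))
  const <- delta_areas(c(`2` = 0.5, `3` = 0.5, `4` = 0.5))
  expect_equal(const$delta[-1], c(0, 0))
  expect_error(delta_areas(c(`2` = 0.4, `4` = 0.6)), "consecutive")
  expect_error(delta_areas(c(`3` = 0.4, `4` = 0.6)), "starting at 2")

  # recomputation oracle on a synthetic cohort's stored areas
  co <- planted_cohort(seed = 3, n_subtypes = 4, samples_per_dataset = 25,
                       n_probes = 80)
  x <- tnbc_submatrix(co)
  cs <- suppressMessages(consensus_subtype(x, k_range = 2:6, n_resamples = 40,
                                           seed = 2))
  a <- cs$areas$area
  brute <- c(a[1], diff(a) / a[-length(a)])
  expect_equal(cs$areas$delta, brute)
})

test_that("choose_k applies the threshold rule and boundary behaviour", {
  d <- tibble::tibble(k = 2:5, area = NA_real_,
                      delta = c(0.60, 0.30, 0.02, 0.01))
  expect_equal(choose_k(d, 0.05), 3)
  d2 <- tibble::tibble(k = 2:4, area = NA_real_, delta = c(0.6, 0.3, 0.2))
  expect_warning(k <- choose_k(d2, 0.05), "k_max")
  expect_equal(k, 4)
  expect_error(choose_k(tibble::tibble(k = 2, area = 1, delta = 1)), "k_max")
})

test_that("final assignment splits a block-diagonal consensus exactly and renames by size", {
  ids <- sprintf("s%02d", 1:12)
  M <- matrix(0, 12, 12, dimnames = list(ids, ids))
  blocks <- list(1:5, 6:9, 10:12)
  for (b in blocks) M[b, b] <- 1
  cm <- structure(list(M = M, I = matrix(10, 12, 12), sample_ids = ids,
                       k = 3, params = list()),
                  class = "tnbc_consensus_matrix")
  lab <- final_assignments(cm, 3)
  expect_equal(lab$subtype[1:5], rep("subtype1", 5))   # largest block first
  expect_equal(lab$subtype[6:9], rep("subtype2", 4))
  expect_equal(lab$subtype[10:12], rep("subtype3", 3))
  expect_error(final_assignments(cm, 1), "at least 2")
  expect_error(final_assignments(cm, 40), "exceeds")
})

test_that("planted 5-subtype structure is recovered end to end with high ARI", {
  co <- planted_cohort(seed = 21)
  norm <- suppressMessages(normalize_per_dataset(co$expr))
  x <- tnbc_submatrix(co, norm)
  f <- filter_by_sd(x, 0.9)
  cs <- suppressMessages(consensus_subtype(subset_probes(x, f$retained),
                                           k_range = 2:8, n_resamples = 200,
                                           seed = 31))
  expect_equal(cs$k, 5)
  truth_lab <- truth_labels_for(co, cs$labels$sample_id)
  ari <- adjusted_rand_index(cs$labels$subtype, truth_lab)
  expect_gte(ari, 0.9)
  # mean consensus within true subtypes dwarfs between-subtype consensus
  cm <- cs$matrices[["5"]]
  same <- outer(truth_lab, truth_lab, "==")
  ut <- upper.tri(cm$M)
  expect_gt(mean(cm$M[same & ut]), 0.9)
  expect_lt(mean(cm$M[!same & ut]), 0.1)

  # in-package ARI matches the mclust reference implementation
  skip_if_not_installed("mclust")
  expect_equal(ari, mclust::adjustedRandIndex(cs$labels$subtype, truth_lab))
})

test_that("CDF area is invariant to sample order on separable data", {
  co <- planted_cohort(seed = 4, n_subtypes = 3, samples_per_dataset = 20,
                       noise_sd = 0.2, n_probes = 60)
  x <- tnbc_submatrix(co)
  perm <- withr::with_seed(8, sample(sample_ids(x)))
  xp <- expr_table(expr_values(x)[, perm], batch = expr_batch(x)[perm])
  a1 <- cdf_and_area(consensus_matrix(x, 3, n_resamples = 60, seed = 9))$area
  a2 <- cdf_and_area(consensus_matrix(xp, 3, n_resamples = 60, seed = 9))$area
  expect_equal(a1, a2, tolerance = 0.02)
})

test_that("recovery degrades monotonically with noise", {
  ari_at <- function(noise) {
    co <- planted_cohort(seed = 12, noise_sd = noise,
                         samples_per_dataset = 30, n_probes = 120)
    x <- tnbc_submatrix(co)
    cs <- suppressMessages(consensus_subtype(x, k_range = 2:6,
                                             n_resamples = 60, seed = 13))
    cm <- cs$matrices[["5"]]
    lab <- final_assignments(cm, 5)
    adjusted_rand_index(lab$subtype, truth_labels_for(co, lab$sample_id))
  }
  a_low <- ari_at(0.3)
  a_mid <- ari_at(1.5)
  a_high <- ari_at(4)
  expect_gte(a_low, a_mid - 0.05)
  expect_gte(a_mid, a_high - 0.05)
  expect_gt(a_low, a_high)
})
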