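test_that("separated point masses are recovered with the variance floor active", {
  vals <- c(rep(2, 100), rep(8, 100))
  fit <- fit_two_component_gmm(vals, seed = 1)
  expect_lt(abs(fit$mu[1] - 2), 0.01)
  expect_lt(abs(fit$mu[2] - 8), 0.01)
  expect_lt(abs(fit$weight[1] - 0.5), 0.01)
  expect_lt(abs(fit$weight[2] - 0.5), 0.01)
  expect_true(all(fit$sd >= sqrt(1e-4) - 1e-12))
})

test_that("EM rejects degenerate inputs", {
  expect_error(fit_two_component_gmm(rnorm(5)), "at least 10")
  expect_error(fit_two_component_gmm(rep(3, 50)), "zero-variance")
  expect_error(fit_two_component_gmm(c(rnorm(20), NA)), "finite")
})

test_that("EM means agree with the grid-search MLE oracle and with mclust", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  x <- withr::with_seed(31, {
    comp <- rbinom(2000, 1, 0.5)
    rnorm(2000, ifelse(comp == 1, 11, 6), 1)
  })
  fit <- fit_two_component_gmm(x, seed = 2)
  oracle <- grid_mle_oracle(x, seq(5, 7, by = 0.1), seq(10, 12, by = 0.1))
  expect_lt(abs(fit$mu[1] - oracle$mu[1]), 0.2)
  expect_lt(abs(fit$mu[2] - oracle$mu[2]), 0.2)

  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$mu), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.05)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-3)
})

test_that("parameter recovery: mean absolute error of means < 0.1 over 20 seeds", {
  errs <- vapply(1:20, function(s) {
    x <- withr::with_seed(1000 + s, {
      comp <- rbinom(1000, 1, 0.5)
      rnorm(1000, ifelse(comp == 1, 10, 5), 1)
    })
    fit <- fit_two_component_gmm(x, seed = s)
    mean(abs(fit$mu - c(5, 10)))
  }, numeric(1))
  expect_lt(mean(errs), 0.1)
})

test_that("posterior_high has the closed form, midpoint symmetry and tail limits", {
  fit <- structure(list(mu = c(5, 10), sd = c(1, 1), weight = c(0.5, 0.5),
                        loglik = 0, converged = TRUE, n_iter = 1, n = 0,
                        values = numeric(0)), class = "tnbc_gmm")
  # symmetric midpoint is exactly 1/2
  expect_identical(posterior_high(7.5, fit), 0.5)
  # closed form at value 10
  num <- 0.5 * dnorm(10, 10, 1)
  den <- num + 0.5 * dnorm(10, 5, 1)
  expect_equal(posterior_high(10, fit), num / den, tolerance = 1e-12)
  # tails
  expect_equal(posterior_high(-1e6, fit), 0)
  expect_equal(posterior_high(1e6, fit), 1)
  # monotone when sds are equal
  grid <- seq(0, 15, by = 0.1)
  expect_true(all(diff(posterior_high(grid, fit)) >= 0))
})

test_that("calls are invariant to component initialization (canonical sort)", {
  x <- withr::with_seed(9, c(rnorm(300, 5), rnorm(300, 10)))
  fits <- lapply(c(1, 7, 23), function(s) fit_two_component_gmm(x, seed = s))
  posts <- vapply(fits, function(f) posterior_high(x, f), numeric(length(x)))
  # restarts may stop at minutely different optima, but never change a call
  expect_identical(posts[, 1] < 0.5, posts[, 2] < 0.5)
  expect_identical(posts[, 1] < 0.5, posts[, 3] < 0.5)
  expect_lt(max(abs(posts[, 1] - posts[, 2])), 1e-3)
  expect_lt(max(abs(posts[, 1] - posts[, 3])), 1e-3)
  for (f in fits) expect_lte(f$mu[1], f$mu[2])
})

test_that("posterior calibration: P(posterior > 0.5) approaches the high weight", {
  fit <- fit_two_component_gmm(
    withr::with_seed(5, c(rnorm(600, 5), rnorm(1400, 10))), seed = 1)
  sim <- withr::with_seed(6, {
    comp <- rbinom(2000, 1, fit$weight[2])
    rnorm(2000, ifelse(comp == 1, fit$mu[2], fit$mu[1]),
          ifelse(comp == 1, fit$sd[2], fit$sd[1]))
  })
  frac <- mean(posterior_high(sim, fit) > 0.5)
  band <- 3 * sqrt(fit$weight[2] * (1 - fit$weight[2]) / 2000)
  expect_lt(abs(frac - fit$weight[2]), band + 0.02)
})

test_that("receptor calls respect the posterior cutoff and match planted truth", {
  co <- generate_cohort(sim_config(
    n_datasets = 2, samples_per_dataset = 300, n_probes = 20,
    receptor_mixture = mostly_tnbc_mixture(0.3, separation = 4),
    n_subtypes = 2, markers_per_subtype = 2, batch_shift_sd = 0, seed = 17
  ))
  calls <- call_receptor_status(co$expr)
  truth <- co$truth$samples
  i <- match(calls$sample_id, truth$sample_id)
  status_agreement <- mean(c(
    calls$er_negative == !truth$er_positive[i],
    calls$pr_negative == !truth$pr_positive[i],
    calls$her2_negative == !truth$her2_positive[i]
  ))
  expect_gte(status_agreement, 0.97)
  # a sample negative on all three markers is TNBC; positive on any is not
  expect_identical(calls$tnbc,
                   calls$er_negative & calls$pr_negative & calls$her2_negative)

  expect_error(call_receptor_status(co$expr, probes = marker_probes(er = "nope")),
               "ER")
})

test_that("positive-control confirmation equals the brute-force quantile rule", {
  co <- generate_cohort(sim_config(
    n_datasets = 1, samples_per_dataset = 400, n_probes = 10,
    receptor_mixture = mostly_tnbc_mixture(0.3, separation = 5),
    n_subtypes = 2, markers_per_subtype = 2, batch_shift_sd = 0, seed = 23
  ))
  calls <- call_receptor_status(co$expr)
  conf <- confirm_against_positive_controls(co$expr, calls, ctrl_quantile = 0.10)

  m <- expr_values(co$expr)
  probes <- marker_probes()
  pass <- rep(TRUE, nrow(calls))
  for (mk in c("ER", "PR", "HER2")) {
    pos <- calls$sample_id[!calls[[paste0(tolower(mk), "_negative")]]]
    thr <- quantile(m[probes[[mk]], pos], 0.10, names = FALSE)
    pass <- pass & m[probes[[mk]], calls$sample_id] < thr
  }
  expect_identical(conf$confirmed, calls$tnbc & pass)
  expect_identical(conf$demoted, calls$tnbc & !pass)
  # flagged, never deleted
  expect_equal(nrow(conf), nrow(calls))

  # a candidate sitting at the control median on ER is demoted
  er_med <- median(m[probes[["ER"]],
                     calls$sample_id[!calls$er_negative]])
  m2 <- m
  cand <- calls$sample_id[calls$tnbc][1]
  m2[probes[["ER"]], cand] <- er_med
  conf2 <- confirm_against_positive_controls(expr_table(m2), calls)
  expect_false(conf2$confirmed[conf2$sample_id == cand])
  expect_true(conf2$demoted[conf2$sample_id == cand])
})

test_that("tidy/glance expose the mixture parameters", {
  fit <- fit_two_component_gmm(c(rep(2, 50), rep(8, 50)), seed = 1)
  td <- tidy(fit)
  expect_identical(td$component, c("low", "high"))
  expect_equal(sum(td$weight), 1)
  gl <- glance(fit)
  expect_identical(names(gl), c("loglik", "converged", "n_iter", "n"))
})
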