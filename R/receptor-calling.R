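#' Fit a two-component Gaussian mixture to one receptor probe
#'
#' Maximum-likelihood EM fit of a two-component univariate Gaussian mixture,
#' the model behind "bimodal filtering" of ER/PR/HER2 expression. The fit is
#' initialized from a 2-means split of the values, with additional jittered
#' restarts; the best restart by log-likelihood is kept. Component variances
#' are floored at `var_floor` to prevent collapse onto point masses, and the
#' returned components are sorted so that `mu_low <= mu_high` (making calls
#' invariant to initialization label swaps).
#'
#' @param values Numeric vector of log2 expression values (>= 10, finite,
#'   non-constant).
#' @param max_iter Maximum EM iterations per start.
#' @param tol Convergence tolerance on the relative log-likelihood change.
#' @param n_starts Number of restarts (first uses the 2-means split, the rest
#'   jitter it).
#' @param var_floor Lower bound on component variances (log2 units squared).
#' @param seed Integer seed controlling the restart jitter.
#' @return An object of class `tnbc_gmm`: a list with `mu`, `sd`, `weight`
#'   (each length-2, low then high component), `loglik`, `converged`,
#'   `n_iter`, `n`, and the input `values`.
#' @export
fit_two_component_gmm <- function(values, max_iter = 500, tol = 1e-8,
                                  n_starts = 5, var_floor = 1e-4, seed = 1L) {
  values <- as.numeric(values)
  if (length(values) < 10) rlang::abort("need at least 10 values to fit the mixture.")
  if (any(!is.finite(values))) rlang::abort("values must be finite.")
  if (stats::sd(values) == 0) rlang::abort("zero-variance input; no mixture to fit.")

  withr::local_seed(seed)
  km <- stats::kmeans(matrix(values, ncol = 1), centers = 2, nstart = 5)
  ord <- order(km$centers)
  base_mu <- as.numeric(km$centers[ord])
  base_w <- pmin(pmax(as.numeric(table(factor(km$cluster, levels = ord))) /
                        length(values), 0.05), 0.95)
  base_w <- base_w / sum(base_w)
  base_var <- vapply(ord, function(cl) {
    v <- stats::var(values[km$cluster == cl])
    if (!is.finite(v)) v <- 0
    max(v, var_floor)
  }, numeric(1))

  best <- NULL
  jitter_sd <- stats::sd(values) / 4
  for (s in seq_len(n_starts)) {
    mu0 <- if (s == 1) base_mu else sort(base_mu + stats::rnorm(2, 0, jitter_sd))
    fit <- em_gmm2(values, mu0, base_var, base_w, max_iter, tol, var_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  ord <- order(best$mu)
  structure(
    list(mu = best$mu[ord], sd = sqrt(best$var[ord]), weight = best$w[ord],
         loglik = best$loglik, converged = best$converged,
         n_iter = best$n_iter, n = length(values), values = values),
    class = "tnbc_gmm"
  )
}

em_gmm2 <- function(x, mu, v, w, max_iter, tol, var_floor) {
  n <- length(x)
  loglik <- -Inf
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    # E step in log space
    l1 <- log(w[1]) + stats::dnorm(x, mu[1], sqrt(v[1]), log = TRUE)
    l2 <- log(w[2]) + stats::dnorm(x, mu[2], sqrt(v[2]), log = TRUE)
    m <- pmax(l1, l2)
    lse <- m + log(exp(l1 - m) + exp(l2 - m))
    r2 <- exp(l2 - lse)
    r1 <- 1 - r2
    new_loglik <- sum(lse)
    # M step
    n1 <- sum(r1); n2 <- sum(r2)
    n1 <- max(n1, 1e-8); n2 <- max(n2, 1e-8)
    mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
    v <- c(max(sum(r1 * (x - mu[1])^2) / n1, var_floor),
           max(sum(r2 * (x - mu[2])^2) / n2, var_floor))
    w <- c(n1, n2) / n
    if (is.finite(loglik) &&
        abs(new_loglik - loglik) <= tol * (abs(loglik) + tol)) {
      loglik <- new_loglik
      converged <- TRUE
      break
    }
    loglik <- new_loglik
  }
  if (!converged) {
    rlang::inform(sprintf(
      "EM did not reach tol %.1e within %d iterations; returning last fit.",
      tol, max_iter))
  }
  list(mu = mu, var = v, w = w, loglik = loglik, converged = converged,
       n_iter = it)
}

#' @export
print.tnbc_gmm <- function(x, ...) {
  cat(sprintf(
    "two-component Gaussian mixture (n = %d)\n  low : mu %.3f sd %.3f w %.3f\n  high: mu %.3f sd %.3f w %.3f\n  loglik %.3f (%s, %d iter)\n",
    x$n, x$mu[1], x$sd[1], x$weight[1], x$mu[2], x$sd[2], x$weight[2],
    x$loglik, if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' Posterior probability of the high (expressed) component
#'
#' `w_high * phi(x; mu_high, sd_high) / sum_c w_c * phi(x; mu_c, sd_c)`,
#' evaluated in log space so the tails behave (the posterior tends to 0 as
#' `x -> -Inf` and, for equal component sds, is monotone non-decreasing in
#' `x`).
#'
#' @param value Numeric vector of log2 expression values.
#' @param fit A `tnbc_gmm` fit.
#' @return Posterior probabilities in \[0, 1\], one per value.
#' @export
posterior_high <- function(value, fit) {
  stopifnot(inherits(fit, "tnbc_gmm"))
  l_low <- log(fit$weight[1]) + stats::dnorm(value, fit$mu[1], fit$sd[1], log = TRUE)
  l_high <- log(fit$weight[2]) + stats::dnorm(value, fit$mu[2], fit$sd[2], log = TRUE)
  stats::plogis(l_high - l_low)
}

#' Call ER/PR/HER2 status and flag TNBC candidates
#'
#' Fits the two-component mixture to each receptor probe across all samples
#' and calls a sample negative for a marker when its posterior probability of
#' the high (expressed) component falls below `cutoff`. A sample is a TNBC
#' candidate when negative on all three markers.
#'
#' @param x An expression table containing all three receptor probes.
#' @param probes Named probe map from [marker_probes()].
#' @param cutoff Posterior cutoff for a negative call (default 0.5).
#' @param ... Passed to [fit_two_component_gmm()].
#' @return A tibble of class `tnbc_receptor_calls`: one row per sample with
#'   columns `sample_id`, `batch`, `<marker>_posterior`, `<marker>_negative`
#'   for ER/PR/HER2, and `tnbc`. The three mixture fits, the probe map and the
#'   cutoff ride along as attributes `fits`, `probes`, `cutoff`.
#' @export
call_receptor_status <- function(x, probes = marker_probes(), cutoff = 0.5,
                                 ...) {
  m <- expr_values(x)
  missing <- probes[!probes %in% rownames(m)]
  if (length(missing) > 0) {
    rlang::abort(sprintf("probe for marker %s not in matrix: %s",
                         paste(names(missing), collapse = "/"),
                         paste(missing, collapse = "/")))
  }
  fits <- list()
  out <- tibble::tibble(sample_id = colnames(m))
  batch <- expr_batch(x)
  out$batch <- if (is.null(batch)) NA_character_ else unname(batch[out$sample_id])
  for (mk in c("ER", "PR", "HER2")) {
    vals <- m[probes[[mk]], ]
    fit <- fit_two_component_gmm(vals, ...)
    fits[[mk]] <- fit
    post <- posterior_high(vals, fit)
    out[[paste0(tolower(mk), "_posterior")]] <- unname(post)
    out[[paste0(tolower(mk), "_negative")]] <- unname(post < cutoff)
  }
  out$tnbc <- out$er_negative & out$pr_negative & out$her2_negative
  attr(out, "fits") <- fits
  attr(out, "probes") <- probes
  attr(out, "cutoff") <- cutoff
  class(out) <- c("tnbc_receptor_calls", class(out))
  out
}

#' Confirm TNBC candidates against positive controls
#'
#' Second-pass "marked reduction" check: a TNBC candidate is retained only if,
#' for every marker, its expression lies strictly below the `ctrl_quantile`
#' quantile of the marker-positive control samples' expression. Demoted
#' candidates are flagged (`confirmed = FALSE`), not deleted.
#'
#' @param x The expression table the calls were made on.
#' @param calls A `tnbc_receptor_calls` tibble from [call_receptor_status()].
#' @param controls Sample IDs to use as positive controls; each marker uses
#'   the subset of these called positive for it. Default (`NULL`) uses, per
#'   marker, all samples called positive.
#' @param ctrl_quantile Quantile of the control expression below which a
#'   candidate counts as markedly reduced (default 0.10).
#' @return The calls tibble with logical columns `confirmed` and `demoted`
#'   added (both `FALSE` for non-candidates and `demoted` only `TRUE` for
#'   rejected candidates).
#' @export
confirm_against_positive_controls <- function(x, calls, controls = NULL,
                                              ctrl_quantile = 0.10) {
  stopifnot(inherits(calls, "tnbc_receptor_calls"))
  probes <- attr(calls, "probes")
  m <- expr_values(x)
  if (!all(calls$sample_id %in% colnames(m))) {
    rlang::abort("calls refer to samples absent from the matrix.")
  }
  pass <- rep(TRUE, nrow(calls))
  for (mk in c("ER", "PR", "HER2")) {
    pos <- calls$sample_id[!calls[[paste0(tolower(mk), "_negative")]]]
    ctrl <- if (is.null(controls)) pos else intersect(controls, pos)
    if (length(ctrl) == 0) {
      rlang::abort(sprintf("no marker-positive control samples for %s.", mk))
    }
    thr <- stats::quantile(m[probes[[mk]], ctrl], ctrl_quantile, names = FALSE)
    pass <- pass & (m[probes[[mk]], calls$sample_id] < thr)
  }
  calls$confirmed <- calls$tnbc & pass
  calls$demoted <- calls$tnbc & !pass
  attr(calls, "ctrl_quantile") <- ctrl_quantile
  calls
}
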