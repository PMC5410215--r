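#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a two-component mixture fit
#'
#' @param x A `tnbc_gmm`.
#' @param ... Unused.
#' @return One row per component: `component`, `mean`, `sd`, `weight`.
#' @export
tidy.tnbc_gmm <- function(x, ...) {
  tibble::tibble(component = c("low", "high"), mean = x$mu, sd = x$sd,
                 weight = x$weight)
}

#' @rdname tidy.tnbc_gmm
#' @return `glance()`: one row with `loglik`, `converged`, `n_iter`, `n`.
#' @export
glance.tnbc_gmm <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, converged = x$converged,
                 n_iter = x$n_iter, n = x$n)
}

#' Tidy consensus subtyping results
#'
#' @param x A `tnbc_consensus` from [consensus_subtype()].
#' @param ... Unused.
#' @return `tidy()`: the per-sample label tibble. `glance()`: one row with the
#'   chosen k, the scanned range and resampling settings.
#' @export
tidy.tnbc_consensus <- function(x, ...) x$labels

#' @rdname tidy.tnbc_consensus
#' @export
glance.tnbc_consensus <- function(x, ...) {
  tibble::tibble(
    k = x$k, k_min = min(x$areas$k), k_max = max(x$areas$k),
    n_samples = nrow(x$labels), n_resamples = x$params$n_resamples,
    subsample_fraction = x$params$subsample_fraction,
    delta_threshold = x$params$delta_threshold
  )
}

#' Tidy an SD filter result
#'
#' @param x A `tnbc_sd_filter`.
#' @param ... Unused.
#' @return The per-probe tibble (`probe_id`, `sd`, `retained`).
#' @export
tidy.tnbc_sd_filter <- function(x, ...) x$stats

#' Tidy a cross-tabulation into long form
#'
#' @param x A `tnbc_crosstab`.
#' @param ... Unused.
#' @return A long tibble: `label_a`, `label_b`, `percent`.
#' @export
tidy.tnbc_crosstab <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"label_a",
                      names_to = "label_b", values_to = "percent")
}

#' Mixture-fit diagnostic plot
#'
#' Histogram of the fitted values with the two scaled component densities and
#' the overall mixture density overlaid.
#'
#' @param object A `tnbc_gmm`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tnbc_gmm <- function(object, bins = 40, ...) {
  df <- tibble::tibble(value = object$values)
  grid <- seq(min(df$value), max(df$value), length.out = 400)
  dens <- purrr::map_dfr(1:2, function(i) {
    tibble::tibble(
      value = grid,
      density = object$weight[i] *
        stats::dnorm(grid, object$mu[i], object$sd[i]),
      component = c("low", "high")[i]
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey80", colour = "grey50") +
    ggplot2::geom_line(data = dens,
                       ggplot2::aes(y = .data$density,
                                    colour = .data$component)) +
    ggplot2::labs(x = "log2 expression", y = "density",
                  title = "two-component mixture fit") +
    ggplot2::theme_minimal()
}

#' Consensus subtyping diagnostic plots
#'
#' `type = "cdf"` draws the per-k consensus CDF curves; `type = "delta"` the
#' proportional area increase against k (with the decision threshold);
#' `type = "consensus"` a tile view of the consensus matrix at the chosen k,
#' samples ordered by the final dendrogram.
#'
#' @param object A `tnbc_consensus`.
#' @param type One of `"cdf"`, `"delta"`, `"consensus"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tnbc_consensus <- function(object,
                                    type = c("cdf", "delta", "consensus"),
                                    ...) {
  type <- match.arg(type)
  if (type == "cdf") {
    df <- purrr::map_dfr(names(object$matrices), function(kk) {
      cdf <- cdf_and_area(object$matrices[[kk]])$cdf
      dplyr::mutate(cdf, k = kk)
    })
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$F,
                                       colour = .data$k)) +
        ggplot2::geom_step() +
        ggplot2::labs(x = "consensus index", y = "CDF",
                      title = "consensus CDF by k") +
        ggplot2::theme_minimal()
    )
  }
  if (type == "delta") {
    return(
      ggplot2::ggplot(object$areas, ggplot2::aes(x = .data$k, y = .data$delta)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::geom_hline(yintercept = object$params$delta_threshold,
                            linetype = "dashed") +
        ggplot2::labs(x = "k", y = "relative increase in CDF area",
                      title = sprintf("delta area (chosen k = %d)", object$k)) +
        ggplot2::theme_minimal()
    )
  }
  cm <- object$matrices[[as.character(object$k)]]
  hc <- stats::hclust(stats::as.dist(1 - cm$M), method = "average")
  ord <- cm$sample_ids[hc$order]
  df <- tibble::as_tibble(as.data.frame(as.table(cm$M)),
                          .name_repair = ~c("s1", "s2", "consensus"))
  df$s1 <- factor(df$s1, levels = ord)
  df$s2 <- factor(df$s2, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s1, y = .data$s2,
                                   fill = .data$consensus)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("consensus matrix, k = %d", object$k)) +
    ggplot2::theme_void()
}

#' Cross-tabulation tile plot
#'
#' @param object A `tnbc_crosstab`.
#' @param ... Unused.
#' @return A ggplot object showing column percentages.
#' @export
autoplot.tnbc_crosstab <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label_b, y = .data$label_a,
                                   fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f", .data$percent)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = "labeling B", y = "labeling A", fill = "%") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
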