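#' Consensus matrix from resampled k-means
#'
#' For each resample, draws `ceiling(subsample_fraction * n)` samples without
#' replacement, partitions them into `k` groups by k-means on the probe
#' values, and accumulates co-cluster and co-inclusion counts. The consensus
#' matrix entry (i, j) is the fraction of co-inclusions in which i and j
#' co-clustered.
#'
#' @param x An expression table (features = probes; typically SD-filtered and
#'   standardized, see [consensus_subtype()]).
#' @param k Number of clusters (2 <= k <= number of samples).
#' @param n_resamples Number of resampling iterations.
#' @param subsample_fraction Fraction of samples drawn per resample (0, 1\].
#' @param seed Integer seed; the run is deterministic given it.
#' @param nstart k-means restarts per resample.
#' @return A list of class `tnbc_consensus_matrix`: `M` (consensus ratios),
#'   `I` (co-inclusion counts), `sample_ids`, `k`, `params`.
#' @export
consensus_matrix <- function(x, k, n_resamples = 1000,
                             subsample_fraction = 0.8, seed = 1L,
                             nstart = 10) {
  m <- expr_values(x)
  n <- ncol(m)
  if (k < 2) rlang::abort("`k` must be at least 2.")
  if (k > n) rlang::abort(sprintf("k = %d exceeds the %d samples.", k, n))
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    rlang::abort("`subsample_fraction` must be in (0, 1].")
  }
  X <- t(m)
  withr::local_seed(seed)
  nsub <- ceiling(subsample_fraction * n)
  co <- matrix(0, n, n)
  inc <- matrix(0, n, n)
  for (b in seq_len(n_resamples)) {
    idx <- if (nsub == n) seq_len(n) else sort(sample.int(n, nsub))
    cl <- kmeans_retry(X[idx, , drop = FALSE], k, nstart)
    inc[idx, idx] <- inc[idx, idx] + 1
    for (g in unique(cl)) {
      mem <- idx[cl == g]
      co[mem, mem] <- co[mem, mem] + 1
    }
  }
  M <- ifelse(inc > 0, co / pmax(inc, 1), 0)
  dimnames(M) <- dimnames(inc) <- list(colnames(m), colnames(m))
  structure(
    list(M = M, I = inc, sample_ids = colnames(m), k = k,
         params = list(n_resamples = n_resamples,
                       subsample_fraction = subsample_fraction,
                       seed = seed, nstart = nstart)),
    class = "tnbc_consensus_matrix"
  )
}

# kmeans occasionally draws duplicate initial centers on data with repeated
# points; retry with fresh draws rather than fail the whole resampling run.
kmeans_retry <- function(X, k, nstart, tries = 20) {
  for (t in seq_len(tries)) {
    res <- try(stats::kmeans(X, centers = k, nstart = nstart, iter.max = 50),
               silent = TRUE)
    if (!inherits(res, "try-error")) return(res$cluster)
  }
  rlang::abort(sprintf(
    "k-means failed %d times (k = %d may exceed the distinct points).",
    tries, k))
}

#' Empirical CDF and area for a consensus matrix
#'
#' The empirical cumulative distribution of the upper-triangle consensus
#' entries, defined over \[0, 1\], and the area under it:
#' `A = sum_i (x_{i+1} - x_i) * CDF(x_i)` over the sorted unique entry values
#' augmented with 0 and 1. A maximally clean consensus (all off-diagonal
#' entries 0) gives area 1.
#'
#' @param cm A `tnbc_consensus_matrix`.
#' @return A list with `cdf` (tibble of `value`, `F`) and `area`.
#' @export
cdf_and_area <- function(cm) {
  stopifnot(inherits(cm, "tnbc_consensus_matrix"))
  v <- cm$M[upper.tri(cm$M)]
  xs <- sort(unique(c(0, v, 1)))
  Fx <- vapply(xs, function(q) mean(v <= q), numeric(1))
  area <- sum(diff(xs) * Fx[-length(Fx)])
  list(cdf = tibble::tibble(value = xs, F = Fx), area = area)
}

#' Proportional increase in CDF area across consecutive k
#'
#' `delta(2) = A(2)`; for k > 2, `delta(k) = (A(k) - A(k-1)) / A(k-1)`.
#'
#' @param areas Named numeric vector (names = k) or a tibble with columns `k`
#'   and `area`, over consecutive k starting at 2.
#' @return A tibble with columns `k`, `area`, `delta`.
#' @export
delta_areas <- function(areas) {
  if (is.data.frame(areas)) {
    stopifnot(all(c("k", "area") %in% names(areas)))
    ks <- as.integer(areas$k)
    a <- areas$area
  } else {
    ks <- as.integer(names(areas))
    a <- as.numeric(areas)
  }
  ord <- order(ks)
  ks <- ks[ord]; a <- a[ord]
  if (length(ks) == 0 || ks[1] != 2L || !all(diff(ks) == 1L)) {
    rlang::abort("`areas` must cover consecutive k values starting at 2.")
  }
  delta <- c(a[1], if (length(a) > 1) diff(a) / a[-length(a)])
  tibble::tibble(k = ks, area = a, delta = delta)
}

#' Choose the number of stable clusters from delta areas
#'
#' Returns the smallest k whose successor brings no marked increase in
#' consensus CDF area: the smallest k with `delta(k + 1) < threshold`. If
#' every increase stays marked, returns `k_max` with a warning.
#'
#' @param deltas Output of [delta_areas()] (or a named delta vector over
#'   k = 2..k_max).
#' @param threshold Relative-increase threshold (default 0.05).
#' @return The chosen k (integer).
#' @export
choose_k <- function(deltas, threshold = 0.05) {
  if (is.data.frame(deltas)) {
    ks <- as.integer(deltas$k); d <- deltas$delta
  } else {
    ks <- as.integer(names(deltas)); d <- as.numeric(deltas)
  }
  ord <- order(ks); ks <- ks[ord]; d <- d[ord]
  k_max <- max(ks)
  if (k_max < 3) rlang::abort("need deltas up to k_max >= 3 to choose k.")
  for (i in seq_along(ks)[-length(ks)]) {
    if (d[i + 1] < threshold) return(ks[i])
  }
  rlang::warn(sprintf(
    "every delta(k) >= %g up to k_max = %d; returning k_max.", threshold, k_max))
  k_max
}

#' Final subtype assignment from a consensus matrix
#'
#' Average-linkage hierarchical clustering on the dissimilarity `1 - M`, cut
#' at `k` groups; groups are renamed `subtype1`, `subtype2`, ... by
#' decreasing size.
#'
#' @param cm A `tnbc_consensus_matrix` (computed at the chosen k).
#' @param k Number of groups to cut (>= 2, <= number of samples).
#' @return A tibble with columns `sample_id`, `subtype`.
#' @export
final_assignments <- function(cm, k) {
  stopifnot(inherits(cm, "tnbc_consensus_matrix"))
  n <- length(cm$sample_ids)
  if (k < 2) rlang::abort("`k` must be at least 2.")
  if (k > n) rlang::abort(sprintf("k = %d exceeds the %d samples.", k, n))
  hc <- stats::hclust(stats::as.dist(1 - cm$M), method = "average")
  cl <- stats::cutree(hc, k = k)
  sizes <- table(cl)
  new_id <- stats::setNames(rank(-as.numeric(sizes), ties.method = "first"),
                            names(sizes))
  tibble::tibble(
    sample_id = cm$sample_ids,
    subtype = sprintf("subtype%d", new_id[as.character(cl)])
  )
}

#' Consensus subtyping over a range of k
#'
#' The full subtyping stage: per-probe standardization (mean 0, SD 1;
#' constant probes dropped with a message), a consensus matrix per k in
#' `k_range`, CDF areas and delta areas, delta-area choice of k, and final
#' average-linkage assignment at the chosen k.
#'
#' @param x An expression table (typically the SD-filtered TNBC submatrix).
#' @param k_range Consecutive integers starting at 2 (default 2:10).
#' @param n_resamples,subsample_fraction,nstart Resampling settings, see
#'   [consensus_matrix()].
#' @param delta_threshold Threshold for [choose_k()].
#' @param seed Master seed; per-k seeds are split from it deterministically.
#' @param standardize Standardize probes before clustering (default TRUE).
#' @return An object of class `tnbc_consensus`: list with `matrices` (per-k
#'   `tnbc_consensus_matrix`), `areas` (tibble k/area/delta), `k` (chosen),
#'   `labels` (tibble sample_id/subtype), `params`.
#' @export
consensus_subtype <- function(x, k_range = 2:10, n_resamples = 1000,
                              subsample_fraction = 0.8,
                              delta_threshold = 0.05, seed = 1L,
                              nstart = 10, standardize = TRUE) {
  k_range <- sort(as.integer(k_range))
  if (k_range[1] != 2L || !all(diff(k_range) == 1L)) {
    rlang::abort("`k_range` must be consecutive integers starting at 2.")
  }
  m <- expr_values(x)
  if (standardize) {
    sds <- apply(m, 1, stats::sd)
    if (any(sds == 0)) {
      rlang::inform(sprintf("dropping %d constant probe(s) before clustering.",
                            sum(sds == 0)))
      m <- m[sds > 0, , drop = FALSE]
      sds <- sds[sds > 0]
    }
    m <- (m - rowMeans(m)) / sds
  }
  xs <- expr_table(m, batch = expr_batch(x))
  k_seeds <- withr::with_seed(seed,
                              sample.int(.Machine$integer.max, length(k_range)))
  matrices <- purrr::map(seq_along(k_range), function(i) {
    consensus_matrix(xs, k = k_range[i], n_resamples = n_resamples,
                     subsample_fraction = subsample_fraction,
                     seed = k_seeds[i], nstart = nstart)
  })
  names(matrices) <- as.character(k_range)
  areas <- stats::setNames(
    vapply(matrices, function(cm) cdf_and_area(cm)$area, numeric(1)),
    as.character(k_range)
  )
  tab <- delta_areas(areas)
  k_hat <- choose_k(tab, threshold = delta_threshold)
  labels <- final_assignments(matrices[[as.character(k_hat)]], k_hat)
  structure(
    list(matrices = matrices, areas = tab, k = k_hat, labels = labels,
         params = list(k_range = k_range, n_resamples = n_resamples,
                       subsample_fraction = subsample_fraction,
                       delta_threshold = delta_threshold, seed = seed,
                       nstart = nstart, standardize = standardize)),
    class = "tnbc_consensus"
  )
}

#' @export
print.tnbc_consensus <- function(x, ...) {
  cat(sprintf(
    "consensus subtyping of %d samples (k scanned %d..%d, %d resamples)\n",
    nrow(x$labels), min(x$areas$k), max(x$areas$k), x$params$n_resamples))
  cat(sprintf("chosen k = %d; subtype sizes: %s\n", x$k,
              paste(sprintf("%s=%d", names(table(x$labels$subtype)),
                            as.integer(table(x$labels$subtype))),
                    collapse = ", ")))
  invisible(x)
}
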