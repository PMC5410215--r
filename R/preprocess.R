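#' Quantile-normalize an expression table
#'
#' Forces every sample to the same value distribution: the reference is the
#' across-sample mean of sorted value vectors, and each sample's values are
#' replaced by the reference values at their within-sample ranks. Ties receive
#' the mean of the reference values at the tied ranks (midrank convention).
#' This is the normalization step of RMA applied at matrix level; delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param x An expression table (no missing values; the load policy removes
#'   them).
#' @return An expression table with identical per-sample value distributions;
#'   probe/sample IDs and batch labels unchanged.
#' @export
quantile_normalize <- function(x) {
  m <- expr_values(x)
  if (ncol(m) < 1) rlang::abort("need at least one sample.")
  if (any(!is.finite(m))) rlang::abort("missing values present; drop them at load.")
  if (ncol(m) == 1) return(x)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  expr_table(out, batch = expr_batch(x))
}

#' Normalize each dataset of a cohort against a common reference
#'
#' Quantile-normalizes the samples of each batch (dataset) against a shared
#' reference distribution: the across-all-samples mean of sorted value
#' vectors. Mapping every dataset to the one common target removes additive
#' per-dataset location shifts while preserving each sample's rank structure,
#' which is what the downstream pooled clustering requires. Batches containing
#' a single sample pass through unchanged (logged), since a one-sample
#' distribution gives that dataset no empirical distribution of its own to
#' correct.
#'
#' @param x An expression table with batch labels (see [expr_table()]).
#' @return An expression table, samples in original order.
#' @export
normalize_per_dataset <- function(x) {
  batch <- expr_batch(x)
  if (is.null(batch)) rlang::abort("batch labels required; see set_batch().")
  m <- expr_values(x)
  if (any(!is.finite(m))) rlang::abort("missing values present; drop them at load.")
  ref <- rowMeans(apply(m, 2, sort))
  out <- m
  for (b in unique(batch)) {
    cols <- which(batch[colnames(m)] == b)
    if (length(cols) == 1) {
      rlang::inform(sprintf(
        "batch '%s' has a single sample; passing through unchanged.", b))
      next
    }
    for (j in cols) out[, j] <- map_to_reference(m[, j], ref)
  }
  expr_table(out, batch = batch)
}

# Map one sample's values onto a sorted reference distribution by rank,
# averaging reference values over tied ranks (midrank convention).
map_to_reference <- function(v, ref) {
  out <- ref[rank(v, ties.method = "first")]
  if (anyDuplicated(v)) out <- stats::ave(out, v, FUN = mean)
  out
}

#' Retain the most variable probes
#'
#' Computes each probe's across-sample standard deviation (denominator n - 1)
#' and retains probes whose SD strictly exceeds the threshold. The shipped
#' default threshold is 0.9 log2 units, the conventional cut for "most
#' differentially expressed" probes ahead of consensus clustering.
#'
#' @param x An expression table with at least two samples.
#' @param threshold Non-negative SD threshold (log2 units); strict inequality.
#' @return A list of class `tnbc_sd_filter`: `stats` (tibble with `probe_id`,
#'   `sd`, `retained`), `retained` (probe IDs), `threshold`.
#' @export
filter_by_sd <- function(x, threshold = 0.9) {
  if (threshold < 0) rlang::abort("`threshold` must be >= 0.")
  m <- expr_values(x)
  if (ncol(m) < 2) rlang::abort("SD undefined with fewer than 2 samples.")
  n <- ncol(m)
  mu <- rowMeans(m)
  sds <- sqrt(pmax(rowSums((m - mu)^2), 0) / (n - 1))
  stats <- tibble::tibble(
    probe_id = rownames(m),
    sd = unname(sds),
    retained = unname(sds > threshold)
  )
  structure(
    list(stats = stats, retained = stats$probe_id[stats$retained],
         threshold = threshold),
    class = "tnbc_sd_filter"
  )
}

#' @export
print.tnbc_sd_filter <- function(x, ...) {
  cat(sprintf("SD filter (threshold %g): retained %d / %d probes\n",
              x$threshold, length(x$retained), nrow(x$stats)))
  invisible(x)
}
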