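#' Centroid-correlation score of one sample against one subtype signature
#'
#' The sample's expression vector is standardized (z-scored across the genes
#' supplied), restricted to the signature genes present, and scored against
#' the signed template (+1 for up genes, -1 for down genes). When the template
#' has both directions the score is the Pearson correlation with the template;
#' for a one-directional signature the template is constant and correlation is
#' undefined, so the score falls back to the mean signed z-score (the centroid
#' score). Either way the score is invariant to monotone affine rescaling of
#' the sample. With fewer than 3 signature genes present the score is
#' undefined (`NA`).
#'
#' @param values Named numeric vector: one sample's (log2) expression across
#'   the measured genes.
#' @param signature A `tnbc_signature` tibble for a single subtype (columns
#'   `direction`, `gene`).
#' @return A single score (or `NA` when fewer than 3 genes overlap).
#' @export
signature_score <- function(values, signature) {
  stopifnot(!is.null(names(values)))
  genes <- intersect(signature$gene, names(values))
  if (length(genes) < 3) return(NA_real_)
  s <- stats::sd(values)
  z <- if (is.na(s) || s == 0) values - mean(values) else (values - mean(values)) / s
  template <- ifelse(
    signature$direction[match(genes, signature$gene)] == "up", 1, -1)
  zg <- z[genes]
  if (stats::sd(template) > 0 && stats::sd(zg) > 0) {
    stats::cor(zg, template)
  } else {
    mean(template * zg)
  }
}

#' Score every sample against every subtype signature
#'
#' @param x An expression table (rows are the measured genes/probes).
#' @param signatures A `tnbc_signature` tibble spanning one or more subtypes.
#' @return A long tibble: `sample_id`, `subtype`, `score`, `n_genes` (overlap
#'   with the matrix), with `score = NA` where the overlap is below 3.
#' @export
signature_scores <- function(x, signatures) {
  if (!is.data.frame(signatures) || nrow(signatures) == 0) {
    rlang::abort("empty signature table.")
  }
  m <- expr_values(x)
  subtypes <- unique(signatures$subtype)
  purrr::map_dfr(subtypes, function(st) {
    sig <- signatures[signatures$subtype == st, ]
    n_genes <- length(intersect(sig$gene, rownames(m)))
    scores <- vapply(seq_len(ncol(m)), function(j) {
      signature_score(stats::setNames(m[, j], rownames(m)), sig)
    }, numeric(1))
    tibble::tibble(sample_id = colnames(m), subtype = st,
                   score = scores, n_genes = n_genes)
  })
}

#' Classify samples by best-correlated subtype signature
#'
#' Each sample is labeled with the subtype whose signature it scores highest
#' against; samples whose best score falls below `min_score`, whose top two
#' scores are closer than `score_gap` (ambiguity guard), or which cannot be
#' scored at all, are labeled `UNS` (unclassified).
#'
#' @param x An expression table.
#' @param signatures A `tnbc_signature` tibble.
#' @param min_score Minimum best score for a confident call (default 0.1).
#' @param score_gap Minimum margin between the top two scores (default 0.02).
#' @return A tibble with `sample_id`, `label`, `best_score`, `margin`, plus
#'   one `score_<subtype>` column per subtype.
#' @export
classify_by_signatures <- function(x, signatures, min_score = 0.1,
                                   score_gap = 0.02) {
  long <- signature_scores(x, signatures)
  wide <- tidyr::pivot_wider(long[, c("sample_id", "subtype", "score")],
                             names_from = "subtype", values_from = "score",
                             names_prefix = "score_")
  score_cols <- setdiff(names(wide), "sample_id")
  sc <- as.matrix(wide[, score_cols])
  label <- character(nrow(sc))
  best <- margin <- numeric(nrow(sc))
  for (i in seq_len(nrow(sc))) {
    v <- sc[i, ]
    ok <- !is.na(v)
    if (!any(ok)) {
      label[i] <- "UNS"; best[i] <- NA_real_; margin[i] <- NA_real_
      next
    }
    ord <- order(v[ok], decreasing = TRUE)
    vals <- v[ok][ord]
    best[i] <- vals[1]
    margin[i] <- if (length(vals) > 1) vals[1] - vals[2] else Inf
    label[i] <- if (best[i] < min_score ||
                    (is.finite(margin[i]) && margin[i] < score_gap)) {
      "UNS"
    } else {
      sub("^score_", "", names(v[ok])[ord[1]])
    }
  }
  dplyr::bind_cols(
    tibble::tibble(sample_id = wide$sample_id, label = label,
                   best_score = best, margin = margin),
    wide[, score_cols]
  )
}

#' Cross-tabulate two labelings as column percentages
#'
#' Entry (r, c) is `100 * |a = r & b = c| / |b = c|`: the percentage of the
#' samples carrying label c under labeling `b` that carry label r under
#' labeling `a`. Every level of `a` (including `UNS`) gets a row, so each
#' column sums to 100.
#'
#' @param labels_a,labels_b Tibbles with `sample_id` plus a label column
#'   (`label` or `subtype`), or named character vectors, over the same sample
#'   set.
#' @return A tibble of class `tnbc_crosstab`: first column `label_a`, one
#'   column per `b` level, percentages; per-column sample counts in the
#'   `counts` attribute.
#' @export
cross_tabulate <- function(labels_a, labels_b) {
  a <- normalize_any_labels(labels_a)
  b <- normalize_any_labels(labels_b)
  if (!setequal(names(a), names(b))) {
    rlang::abort("the two labelings must cover the same sample set.")
  }
  b <- b[names(a)]
  tab <- table(a = a, b = b)
  counts <- colSums(tab)
  pct <- sweep(tab, 2, pmax(counts, 1), "/") * 100
  out <- tibble::as_tibble(as.data.frame.matrix(pct), rownames = "label_a")
  attr(out, "counts") <- counts
  class(out) <- c("tnbc_crosstab", class(out))
  out
}

normalize_any_labels <- function(labels) {
  if (is.data.frame(labels)) {
    col <- intersect(c("label", "subtype"), names(labels))[1]
    if (is.na(col) || !"sample_id" %in% names(labels)) {
      rlang::abort("label tibbles need `sample_id` and `label`/`subtype` columns.")
    }
    stats::setNames(as.character(labels[[col]]), labels$sample_id)
  } else {
    if (is.null(names(labels))) rlang::abort("label vectors must be named by sample.")
    stats::setNames(as.character(labels), names(labels))
  }
}
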