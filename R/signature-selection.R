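#' Per-probe subtype-versus-rest statistics
#'
#' For one subtype against all other labeled samples, computes per probe:
#' the linear fold change `2^(mean_subtype - mean_rest)` of log2 values, the
#' fraction of subtype samples whose value lies strictly above (and, mirrored,
#' strictly below) the rest mean, and a Welch two-sample t-test p-value.
#' Constant probes (zero variance in both groups, equal means) get p = 1 and
#' fold change 1; ties with the rest mean count as non-positive differences.
#'
#' @param x An expression table.
#' @param labels A tibble with columns `sample_id`, `subtype` (or a named
#'   character vector). Samples without a label are ignored.
#' @param subtype The subtype to contrast against the rest.
#' @return A tibble with columns `probe_id`, `subtype`, `mean_subtype`,
#'   `mean_rest`, `log2_fc`, `fold_change`, `frac_above`, `frac_below`,
#'   `p_value`.
#' @export
subtype_vs_rest_stats <- function(x, labels, subtype) {
  lab <- normalize_labels(labels)
  m <- expr_values(x)
  lab <- lab[names(lab) %in% colnames(m)]
  in_grp <- names(lab)[lab == subtype]
  rest <- names(lab)[lab != subtype]
  if (length(in_grp) < 3 || length(rest) < 3) {
    rlang::abort(sprintf(
      "subtype '%s' needs >= 3 samples in group (%d) and rest (%d).",
      subtype, length(in_grp), length(rest)))
  }
  X1 <- m[, in_grp, drop = FALSE]
  X2 <- m[, rest, drop = FALSE]
  n1 <- ncol(X1); n2 <- ncol(X2)
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- rowSums((X1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((X2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  tibble::tibble(
    probe_id = rownames(m),
    subtype = subtype,
    mean_subtype = unname(m1),
    mean_rest = unname(m2),
    log2_fc = unname(m1 - m2),
    fold_change = unname(2^(m1 - m2)),
    frac_above = unname(rowMeans(X1 > m2)),
    frac_below = unname(rowMeans(X1 < m2)),
    p_value = unname(p)
  )
}

normalize_labels <- function(labels) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("sample_id", "subtype") %in% names(labels)))
    lab <- stats::setNames(as.character(labels$subtype), labels$sample_id)
  } else {
    if (is.null(names(labels))) {
      rlang::abort("`labels` must be a sample_id/subtype tibble or a named vector.")
    }
    lab <- as.character(labels)
    names(lab) <- names(labels)
  }
  lab[!is.na(lab)]
}

#' Select subtype-specific signature probes by the three-criterion filter
#'
#' Up-regulated probes must satisfy fold change > `fc_up`, fraction of subtype
#' samples above the rest mean > `min_fraction`, and p < `max_p`;
#' down-regulated probes must satisfy fold change < `fc_down`, fraction below
#' the rest mean > `min_fraction` (the mirrored concordance rule), and
#' p < `max_p`. All inequalities are strict. When several probes map to one
#' gene, only the strongest (largest |log2 fold change|) survives per subtype.
#' Defaults are the conventional cuts: 1.75 / 0.5 / 0.80 / 1e-4. No multiple-
#' testing correction is applied by default; set `adjust = "BH"` for
#' Benjamini-Hochberg on the p-values before thresholding.
#'
#' @param stats Output of [subtype_vs_rest_stats()] (may stack several
#'   subtypes).
#' @param fc_up Upregulation fold-change threshold (> 1).
#' @param fc_down Downregulation fold-change threshold (in (0, 1)).
#' @param min_fraction Concordance-fraction threshold.
#' @param max_p p-value threshold.
#' @param gene_map Optional tibble `probe_id`, `gene` for probe-to-gene
#'   collapse; by default every probe is its own gene.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `tnbc_signature` tibble: columns `subtype`, `direction`, `gene`,
#'   `probe_id`, `fold_change`, `p_value`.
#' @export
select_signature <- function(stats, fc_up = 1.75, fc_down = 0.5,
                             min_fraction = 0.8, max_p = 1e-4,
                             gene_map = NULL, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!(fc_up > 1 && fc_down < 1 && fc_down > 0)) {
    rlang::abort("need fc_up > 1 > fc_down > 0.")
  }
  p <- stats$p_value
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  up <- stats$fold_change > fc_up & stats$frac_above > min_fraction & p < max_p
  dn <- stats$fold_change < fc_down & stats$frac_below > min_fraction & p < max_p
  sel <- dplyr::bind_rows(
    dplyr::mutate(stats[up, ], direction = "up"),
    dplyr::mutate(stats[dn, ], direction = "down")
  )
  if (is.null(gene_map)) {
    sel$gene <- sel$probe_id
  } else {
    stopifnot(all(c("probe_id", "gene") %in% names(gene_map)))
    sel <- dplyr::left_join(sel, gene_map, by = "probe_id")
    sel$gene <- dplyr::coalesce(sel$gene, sel$probe_id)
  }
  out <- sel |>
    dplyr::group_by(.data$subtype, .data$gene) |>
    dplyr::slice_max(abs(.data$log2_fc), n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$subtype, .data$direction,
                   dplyr::desc(abs(.data$log2_fc))) |>
    dplyr::select("subtype", "direction", "gene", "probe_id",
                  "fold_change", "p_value")
  class(out) <- c("tnbc_signature", class(out))
  out
}
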