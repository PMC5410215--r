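#' Pipeline configuration
#'
#' Collects every stage parameter with the conventional defaults: receptor
#' probes per [marker_probes()], posterior cutoff 0.5, positive-control
#' quantile 0.10, SD filter 0.9, k scanned 2..10 with 1000 resamples at
#' subsample fraction 0.8 and delta-area threshold 0.05, signature thresholds
#' 1.75 / 0.5 / 0.80 / 1e-4, classifier thresholds 0.1 / 0.02, one master
#' seed. `tnbc_config_from_yaml()` reads the same fields from a YAML file.
#'
#' @param probes Receptor probe map ([marker_probes()]).
#' @param cutoff Posterior cutoff for a negative receptor call.
#' @param use_positive_controls Run the positive-control confirmation pass.
#' @param ctrl_quantile Positive-control quantile for "marked reduction".
#' @param sd_threshold SD filter threshold (log2 units).
#' @param k_min,k_max Range of k scanned by consensus clustering.
#' @param n_resamples,subsample_fraction,nstart Consensus resampling settings.
#' @param delta_threshold Delta-area threshold for choosing k.
#' @param fc_up,fc_down,min_fraction,max_p Signature-selection thresholds.
#' @param min_score,score_gap Classifier thresholds.
#' @param seed Master seed; stage seeds are split from it deterministically.
#' @return A list of class `tnbc_config`.
#' @export
tnbc_config <- function(probes = marker_probes(),
                        cutoff = 0.5,
                        use_positive_controls = TRUE,
                        ctrl_quantile = 0.10,
                        sd_threshold = 0.9,
                        k_min = 2, k_max = 10,
                        n_resamples = 1000,
                        subsample_fraction = 0.8,
                        nstart = 10,
                        delta_threshold = 0.05,
                        fc_up = 1.75, fc_down = 0.5,
                        min_fraction = 0.8, max_p = 1e-4,
                        min_score = 0.1, score_gap = 0.02,
                        seed = 1L) {
  cfg <- list(
    probes = probes, cutoff = cutoff,
    use_positive_controls = isTRUE(use_positive_controls),
    ctrl_quantile = ctrl_quantile, sd_threshold = sd_threshold,
    k_min = as.integer(k_min), k_max = as.integer(k_max),
    n_resamples = as.integer(n_resamples),
    subsample_fraction = subsample_fraction, nstart = as.integer(nstart),
    delta_threshold = delta_threshold,
    fc_up = fc_up, fc_down = fc_down,
    min_fraction = min_fraction, max_p = max_p,
    min_score = min_score, score_gap = score_gap,
    seed = as.integer(seed)
  )
  if (cfg$k_min != 2L) rlang::abort("k_min must be 2 (delta areas start there).")
  if (cfg$k_max < 3L) rlang::abort("k_max must be at least 3.")
  if (cfg$cutoff <= 0 || cfg$cutoff >= 1) rlang::abort("cutoff must be in (0,1).")
  if (cfg$sd_threshold < 0) rlang::abort("sd_threshold must be >= 0.")
  if (!(cfg$fc_up > 1 && cfg$fc_down > 0 && cfg$fc_down < 1)) {
    rlang::abort("need fc_up > 1 > fc_down > 0.")
  }
  if (cfg$subsample_fraction <= 0 || cfg$subsample_fraction > 1) {
    rlang::abort("subsample_fraction must be in (0,1].")
  }
  class(cfg) <- "tnbc_config"
  cfg
}

#' @rdname tnbc_config
#' @param path Path to a YAML file whose keys match the arguments above.
#' @export
tnbc_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(tnbc_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    rlang::abort(sprintf("unknown config key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  if (!is.null(vals$probes)) vals$probes <- unlist(vals$probes)
  do.call(tnbc_config, vals)
}

#' Run the whole subtyping pipeline
#'
#' Executes merge-ready input through the full protocol: per-dataset
#' normalization, mixture-based receptor calling, positive-control
#' confirmation, SD filtering of the TNBC submatrix, consensus subtyping with
#' delta-area choice of k, per-subtype signature selection, and (when a
#' reference signature table is supplied or selection succeeds)
#' centroid-correlation classification with a cross-tabulation of classifier
#' labels against consensus subtypes. Fully reproducible given the config
#' seed.
#'
#' @param x An expression table (use [merge_cohorts()] first for multi-cohort
#'   input). Batch labels trigger per-dataset normalization; without them a
#'   plain quantile normalization is applied.
#' @param config A [tnbc_config()].
#' @param reference_signatures Optional `tnbc_signature` tibble of published
#'   subtype gene lists to classify against; default uses the pipeline's own
#'   selected signatures.
#' @return An object of class `tnbc_run`: list with `report` (all counts,
#'   parameters and proportions; serializable via [write_run_report()]),
#'   `calls`, `sd_filter`, `consensus`, `signatures`, `classified`,
#'   `crosstab`.
#' @export
run_all <- function(x, config = tnbc_config(), reference_signatures = NULL) {
  stopifnot(inherits(config, "tnbc_config"))
  t0 <- Sys.time()
  stage_seeds <- withr::with_seed(config$seed,
                                  sample.int(.Machine$integer.max, 3))
  n_samples <- length(sample_ids(x))

  stage <- "normalization"
  res <- run_stage(stage, {
    if (is.null(expr_batch(x))) quantile_normalize(x) else normalize_per_dataset(x)
  })
  normalized <- res

  stage <- "receptor_calling"
  calls <- run_stage(stage, {
    call_receptor_status(normalized, probes = config$probes,
                         cutoff = config$cutoff, seed = stage_seeds[1])
  })

  stage <- "positive_control_confirmation"
  calls <- run_stage(stage, {
    if (config$use_positive_controls) {
      confirm_against_positive_controls(normalized, calls,
                                        ctrl_quantile = config$ctrl_quantile)
    } else {
      calls$confirmed <- calls$tnbc
      calls$demoted <- FALSE
      calls
    }
  })
  tnbc_ids <- calls$sample_id[calls$confirmed]
  n_tnbc <- length(tnbc_ids)
  n_demoted <- sum(calls$demoted)
  n_non_tnbc <- sum(!calls$tnbc)

  stage <- "sd_filter"
  if (n_tnbc < config$k_max + 1) {
    rlang::abort(sprintf(
      "stage %s: only %d confirmed TNBC samples; need more than k_max = %d.",
      stage, n_tnbc, config$k_max))
  }
  tn_expr <- expr_table(expr_values(normalized)[, tnbc_ids, drop = FALSE],
                        batch = expr_batch(normalized)[tnbc_ids])
  sdf <- run_stage(stage, filter_by_sd(tn_expr, threshold = config$sd_threshold))
  if (length(sdf$retained) < 2) {
    rlang::abort(sprintf("stage %s: fewer than 2 probes retained.", stage))
  }
  filtered <- subset_probes(tn_expr, sdf$retained)

  stage <- "consensus_subtyping"
  cons <- run_stage(stage, {
    consensus_subtype(filtered, k_range = config$k_min:config$k_max,
                      n_resamples = config$n_resamples,
                      subsample_fraction = config$subsample_fraction,
                      delta_threshold = config$delta_threshold,
                      seed = stage_seeds[2], nstart = config$nstart)
  })

  stage <- "signature_selection"
  signatures <- run_stage(stage, {
    usable <- names(which(table(cons$labels$subtype) >= 3))
    usable <- usable[vapply(usable, function(st)
      sum(cons$labels$subtype != st) >= 3, logical(1))]
    stats <- purrr::map_dfr(usable, function(st)
      subtype_vs_rest_stats(tn_expr, cons$labels, st))
    select_signature(stats, fc_up = config$fc_up, fc_down = config$fc_down,
                     min_fraction = config$min_fraction, max_p = config$max_p)
  })

  stage <- "classification"
  ref <- if (is.null(reference_signatures)) signatures else reference_signatures
  classified <- crosstab <- NULL
  if (nrow(ref) > 0) {
    classified <- run_stage(stage, {
      classify_by_signatures(tn_expr, ref, min_score = config$min_score,
                             score_gap = config$score_gap)
    })
    crosstab <- cross_tabulate(classified, cons$labels)
  } else {
    rlang::inform("no signatures available; skipping classification.")
  }

  subtype_counts <- as.list(table(cons$labels$subtype))
  classified_counts <- if (is.null(classified)) NULL else
    as.list(table(classified$label))
  assigned <- if (is.null(classified)) character(0) else
    classified$label[classified$label != "UNS"]
  report <- list(
    parameters = unclass(config),
    counts = list(
      n_samples = n_samples,
      n_non_tnbc = n_non_tnbc,
      n_demoted = n_demoted,
      n_tnbc = n_tnbc,
      n_probes = length(probe_ids(x)),
      n_probes_retained = length(sdf$retained),
      subtype_counts = subtype_counts,
      classified_counts = classified_counts
    ),
    chosen_k = cons$k,
    areas = as.data.frame(cons$areas),
    consensus_subtype_pct = lapply(subtype_counts, function(n)
      100 * n / max(n_tnbc, 1)),
    classified_subtype_pct = if (length(assigned) > 0)
      as.list(100 * table(assigned) / length(assigned)) else NULL,
    n_signature_probes = nrow(signatures),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z")
  )
  structure(
    list(report = report, calls = calls, sd_filter = sdf, consensus = cons,
         signatures = signatures, classified = classified,
         crosstab = crosstab),
    class = "tnbc_run"
  )
}

run_stage <- function(stage, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    rlang::abort(sprintf("stage %s failed: %s", stage, conditionMessage(e)),
                 parent = e)
  })
  rlang::inform(sprintf("[%s] done in %.1fs", stage,
                        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' @export
print.tnbc_run <- function(x, ...) {
  co <- x$report$counts
  cat(sprintf(
    "TNBC subtyping run: %d samples -> %d TNBC (%d demoted, %d receptor-positive)\n",
    co$n_samples, co$n_tnbc, co$n_demoted, co$n_non_tnbc))
  cat(sprintf("probes: %d -> %d after SD filter; chosen k = %d\n",
              co$n_probes, co$n_probes_retained, x$report$chosen_k))
  if (!is.null(x$report$consensus_subtype_pct)) {
    pct <- unlist(x$report$consensus_subtype_pct)
    cat("consensus subtype proportions (% of TNBC):\n")
    for (nm in names(pct)) cat(sprintf("  %s: %.2f%%\n", nm, pct[nm]))
  }
  invisible(x)
}

#' Write the machine-readable run report
#'
#' @param run A `tnbc_run` from [run_all()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(run, path) {
  stopifnot(inherits(run, "tnbc_run"))
  jsonlite::write_json(run$report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Render a clustered heat map to an image file
#'
#' Presentational only: writes a [pheatmap::pheatmap()] heat map of an
#' expression table (or plain matrix) to `path`. No values are derived from
#' the image.
#'
#' @param x An expression table or numeric matrix.
#' @param path Output image path (extension selects the device, e.g. `.png`).
#' @param row_order Optional row (probe) order.
#' @param col_labels Optional per-sample annotation (named character vector);
#'   shown as a column annotation bar.
#' @param ... Passed through to [pheatmap::pheatmap()].
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(x, path, row_order = NULL, col_labels = NULL, ...) {
  m <- if (is.matrix(x)) x else expr_values(x)
  if (!is.null(row_order)) m <- m[row_order, , drop = FALSE]
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, 2) != 0) {
    rlang::abort(sprintf("cannot write heat map to '%s'.", path))
  }
  ann <- NA
  if (!is.null(col_labels)) {
    ann <- data.frame(group = unname(col_labels[colnames(m)]),
                      row.names = colnames(m))
  }
  pheatmap::pheatmap(m, filename = path, annotation_col = ann, silent = TRUE,
                     ...)
  invisible(path)
}
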