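#' Build an expression table
#'
#' The package's shared data model for probe-level expression: a tibble whose
#' first column is `probe_id` and whose remaining columns are samples, holding
#' log2 intensities. A per-sample dataset (batch) label is carried in the
#' `"batch"` attribute as a named character vector; [expr_batch()] and
#' [set_batch()] access it. All computation in the package is on log2 scale;
#' linear-scale quantities (fold changes) are derived by exponentiation at the
#' point of use.
#'
#' @param values Numeric matrix, probes x samples, with unique rownames
#'   (probe IDs) and unique colnames (sample IDs). Log2 intensities.
#' @param batch Optional per-sample dataset label: character vector of length
#'   `ncol(values)`, either unnamed (taken in column order) or named by sample.
#' @return A tibble of class `tnbc_expr` with columns `probe_id`, then one
#'   column per sample.
#' @examples
#' m <- matrix(rnorm(6, 8), 3, 2, dimnames = list(paste0("p", 1:3), c("s1", "s2")))
#' expr_table(m, batch = c("GSE1", "GSE1"))
#' @export
expr_table <- function(values, batch = NULL) {
  if (!is.matrix(values) || !is.numeric(values)) {
    rlang::abort("`values` must be a numeric matrix (probes x samples).")
  }
  probes <- rownames(values)
  samples <- colnames(values)
  if (is.null(probes) || is.null(samples)) {
    rlang::abort("`values` must have rownames (probes) and colnames (samples).")
  }
  check_unique(probes, "probe")
  check_unique(samples, "sample")
  if (any(!is.finite(values))) {
    rlang::abort("expression values must be finite (no missing entries).")
  }
  out <- dplyr::bind_cols(
    tibble::tibble(probe_id = probes),
    tibble::as_tibble(values, .name_repair = "minimal")
  )
  if (!is.null(batch)) {
    batch <- as.character(batch)
    if (is.null(names(batch))) {
      if (length(batch) != length(samples)) {
        rlang::abort("`batch` must have one label per sample.")
      }
      names(batch) <- samples
    }
    if (!setequal(names(batch), samples)) {
      rlang::abort("names of `batch` must match the sample IDs.")
    }
    batch <- batch[samples]
  }
  attr(out, "batch") <- batch
  class(out) <- c("tnbc_expr", class(out))
  out
}

check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    rlang::abort(sprintf(
      "duplicate %s ID(s): %s", what, paste(dup, collapse = ", ")
    ))
  }
  invisible(ids)
}

#' Extract the numeric matrix / sample metadata from an expression table
#'
#' @param x An expression table from [expr_table()] or [read_expression_tsv()].
#' @return `expr_values()`: the probes x samples numeric matrix;
#'   `expr_batch()`: the named per-sample batch vector (or `NULL`);
#'   `sample_ids()` / `probe_ids()`: character vectors.
#' @export
expr_values <- function(x) {
  stopifnot(is.data.frame(x), names(x)[1] == "probe_id")
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- x$probe_id
  m
}

#' @rdname expr_values
#' @export
expr_batch <- function(x) attr(x, "batch", exact = TRUE)

#' @rdname expr_values
#' @export
sample_ids <- function(x) setdiff(names(x), "probe_id")

#' @rdname expr_values
#' @export
probe_ids <- function(x) x$probe_id

#' @rdname expr_values
#' @param batch New batch labels, as in [expr_table()].
#' @export
set_batch <- function(x, batch) {
  expr_table(expr_values(x), batch = batch)
}

#' Subset an expression table to a set of probes
#'
#' @param x An expression table.
#' @param probes Character vector of probe IDs to keep (all must be present);
#'   row order follows `probes`.
#' @return An expression table restricted to `probes`.
#' @export
subset_probes <- function(x, probes) {
  missing <- setdiff(probes, probe_ids(x))
  if (length(missing) > 0) {
    rlang::abort(sprintf("probe(s) not in matrix: %s",
                         paste(utils::head(missing, 5), collapse = ", ")))
  }
  expr_table(expr_values(x)[probes, , drop = FALSE], batch = expr_batch(x))
}

#' Read a tab-separated expression matrix
#'
#' Expects a plain TSV: first row sample IDs (first cell is the probe-ID column
#' header), first column probe IDs. An optional second header line starting
#' with `#batch` carries per-sample dataset labels (the dialect written by
#' [write_expression_tsv()]). Rows containing any non-numeric or missing cell
#' are dropped with a warning (the loader's missing-value policy).
#'
#' @param path Path to the TSV file.
#' @param log_transformed If `FALSE`, values are linear intensities and
#'   `log2(x + 1)` is applied; if `TRUE` (default) values are already log2.
#' @return An expression table (see [expr_table()]).
#' @export
read_expression_tsv <- function(path, log_transformed = TRUE) {
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  head_lines <- readLines(path, n = 2L)
  if (length(head_lines) == 0 || !nzchar(head_lines[1])) {
    rlang::abort(sprintf("empty expression file: %s", path))
  }
  header <- strsplit(head_lines[1], "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  if (length(samples) == 0) rlang::abort("no sample columns in header.")
  check_unique(samples, "sample")

  has_batch <- length(head_lines) >= 2 && startsWith(head_lines[2], "#batch")
  batch <- NULL
  if (has_batch) {
    bfields <- strsplit(head_lines[2], "\t", fixed = TRUE)[[1]][-1]
    if (length(bfields) != length(samples)) {
      rlang::abort("#batch line must have one label per sample.")
    }
    batch <- stats::setNames(bfields, samples)
  }

  body <- readr::read_tsv(
    path,
    skip = if (has_batch) 2L else 1L,
    col_names = c("probe_id", samples),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(body) == 0) rlang::abort(sprintf("expression file has no data rows: %s", path))
  check_unique(body$probe_id, "probe")

  vals <- suppressWarnings(
    vapply(body[-1], function(col) as.numeric(col), numeric(nrow(body)))
  )
  vals <- matrix(vals, nrow = nrow(body),
                 dimnames = list(body$probe_id, samples))
  bad <- rowSums(!is.finite(vals)) > 0
  if (any(bad)) {
    rlang::warn(sprintf(
      "dropping %d row(s) with non-numeric or missing values (e.g. %s)",
      sum(bad), paste(utils::head(body$probe_id[bad], 3), collapse = ", ")
    ))
    vals <- vals[!bad, , drop = FALSE]
  }
  if (nrow(vals) == 0) rlang::abort("no usable (fully numeric) rows in file.")
  if (!log_transformed) vals <- log2(vals + 1)
  expr_table(vals, batch = batch)
}

#' Write an expression table as TSV
#'
#' Writes the dialect read by [read_expression_tsv()]: a single header row of
#' sample IDs, an optional `#batch` sidecar line with per-sample dataset
#' labels, then one row per probe. Values are written with enough digits for a
#' lossless round trip.
#'
#' @param x An expression table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  m <- expr_values(x)
  if (nrow(m) == 0) rlang::abort("refusing to write an expression table with no probes.")
  if (ncol(m) == 0) rlang::abort("refusing to write an expression table with no samples.")
  lines <- paste(c("probe_id", colnames(m)), collapse = "\t")
  batch <- expr_batch(x)
  if (!is.null(batch)) {
    lines <- c(lines, paste(c("#batch", unname(batch[colnames(m)])), collapse = "\t"))
  }
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], formatC(m[i, ], format = "g", digits = 17)),
          collapse = "\t")
  }, character(1))
  res <- try(writeLines(c(lines, body), path), silent = TRUE)
  if (inherits(res, "try-error")) {
    rlang::abort(sprintf("could not write to '%s'", path))
  }
  invisible(path)
}

#' Merge several cohorts into one expression table
#'
#' Restricts probes to the intersection across cohorts (in the first cohort's
#' order), concatenates samples, and sets each sample's batch label to its
#' source cohort (list names when present, else `cohort1`, `cohort2`, ...).
#'
#' @param cohorts A list of expression tables (length >= 1), optionally named.
#' @return A merged expression table with batch labels.
#' @export
merge_cohorts <- function(cohorts) {
  if (!is.list(cohorts) || length(cohorts) == 0 || is.data.frame(cohorts)) {
    rlang::abort("`cohorts` must be a non-empty list of expression tables.")
  }
  if (length(cohorts) == 1) return(cohorts[[1]])
  labels <- names(cohorts)
  if (is.null(labels)) labels <- rep("", length(cohorts))
  labels <- ifelse(nzchar(labels), labels, paste0("cohort", seq_along(cohorts)))

  probes <- Reduce(intersect, lapply(cohorts, probe_ids))
  if (length(probes) == 0) rlang::abort("empty probe intersection across cohorts.")
  all_samples <- unlist(lapply(cohorts, sample_ids), use.names = FALSE)
  check_unique(all_samples, "sample")

  mats <- lapply(cohorts, function(co) expr_values(co)[probes, , drop = FALSE])
  merged <- do.call(cbind, mats)
  batch <- stats::setNames(
    rep(labels, vapply(cohorts, function(co) length(sample_ids(co)), integer(1))),
    all_samples
  )
  expr_table(merged, batch = batch)
}

#' Read subtype signature gene lists
#'
#' Two dialects are supported: a TSV with header columns `subtype`,
#' `direction` (`up` or `down`) and `gene` (extra columns are kept), or a
#' GMT-style file (one set per line, `NAME<TAB>description<TAB>gene...`) where
#' the set name ends in `_up` or `_down`. Duplicate (subtype, direction, gene)
#' rows are collapsed with a warning; a gene appearing in both the up and down
#' list of the same subtype is an error.
#'
#' @param path Path to the signature file.
#' @param format `"auto"` (by extension), `"tsv"` or `"gmt"`.
#' @return A tibble of class `tnbc_signature` with columns `subtype`,
#'   `direction`, `gene` (plus any extra TSV columns).
#' @export
read_signature_lists <- function(path, format = c("auto", "tsv", "gmt")) {
  format <- match.arg(format)
  if (!file.exists(path)) rlang::abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  }
  if (format == "gmt") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) rlang::abort(sprintf("empty signature file: %s", path))
    rows <- purrr::map_dfr(lines, function(ln) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      nm <- f[1]
      if (!grepl("_(up|down)$", nm, ignore.case = TRUE)) {
        rlang::abort(sprintf(
          "GMT set name '%s' must end in _up or _down (direction token).", nm))
      }
      direction <- tolower(sub(".*_(up|down)$", "\\1", nm, ignore.case = TRUE))
      subtype <- sub("_(up|down)$", "", nm, ignore.case = TRUE)
      genes <- f[-(1:2)]
      tibble::tibble(subtype = subtype, direction = direction, gene = genes)
    })
  } else {
    rows <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                            progress = FALSE)
    if (nrow(rows) == 0) rlang::abort(sprintf("empty signature file: %s", path))
    need <- c("subtype", "direction", "gene")
    if (!all(need %in% names(rows))) {
      rlang::abort("signature TSV must have columns: subtype, direction, gene.")
    }
    bad <- setdiff(unique(rows$direction), c("up", "down"))
    if (length(bad) > 0) {
      rlang::abort(sprintf("unknown direction token(s): %s",
                           paste(bad, collapse = ", ")))
    }
  }
  ndup <- sum(duplicated(rows[c("subtype", "direction", "gene")]))
  if (ndup > 0) {
    rlang::warn(sprintf("collapsing %d duplicate signature entrie(s).", ndup))
    rows <- dplyr::distinct(rows, .data$subtype, .data$direction, .data$gene,
                            .keep_all = TRUE)
  }
  both <- rows |>
    dplyr::distinct(.data$subtype, .data$direction, .data$gene) |>
    dplyr::count(.data$subtype, .data$gene) |>
    dplyr::filter(.data$n > 1)
  if (nrow(both) > 0) {
    rlang::abort(sprintf(
      "gene(s) in both up and down lists of the same subtype: %s",
      paste(utils::head(paste(both$subtype, both$gene, sep = "/"), 5), collapse = ", ")))
  }
  class(rows) <- c("tnbc_signature", class(rows))
  rows
}

#' Write signature gene lists as 3-column TSV
#'
#' @param signatures A `tnbc_signature` tibble (columns subtype, direction, gene).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_lists <- function(signatures, path) {
  stopifnot(all(c("subtype", "direction", "gene") %in% names(signatures)))
  readr::write_tsv(signatures[, c("subtype", "direction", "gene")], path,
                   progress = FALSE)
  invisible(path)
}

#' Probe-to-marker map for the three receptor markers
#'
#' Defaults to the canonical Affymetrix probes for ER (205225_at, ESR1),
#' PR (208305_at, PGR) and HER2 (216836_s_at, ERBB2).
#'
#' @param er,pr,her2 Probe IDs for each marker.
#' @return A named character vector with entries `ER`, `PR`, `HER2`.
#' @export
marker_probes <- function(er = "205225_at", pr = "208305_at",
                          her2 = "216836_s_at") {
  c(ER = er, PR = pr, HER2 = her2)
}

#' Packaged bookkeeping and validation tables
#'
#' `tnbc_dataset_counts()` returns the per-dataset breast-cancer / TNBC sample
#' counts of the compiled public cohorts (one row per GEO accession, with a
#' `cohort` column separating the non-Asian and Taiwanese arms).
#' `tnbc_validation_signature()` returns the packaged 47-probe, five-subtype
#' (IM, MSL, M, LAR, BL) validation gene list. `tnbc_reference_crosstab()`
#' returns the published column-percentage cross-tabulation of the five-subtype
#' labeling against the six Lehmann subtypes.
#'
#' @return A tibble (for the signature, of class `tnbc_signature`).
#' @export
tnbc_dataset_counts <- function() {
  readr::read_tsv(
    system.file("extdata", "dataset_counts.tsv", package = "tnbcsubtyper"),
    col_types = readr::cols(
      cohort = "c", accession = "c", country = "c",
      bc_cases = "i", tnbc_cases = "i"
    ),
    progress = FALSE
  )
}

#' @rdname tnbc_dataset_counts
#' @export
tnbc_validation_signature <- function() {
  read_signature_lists(
    system.file("extdata", "validation_signature_47.tsv", package = "tnbcsubtyper")
  )
}

#' @rdname tnbc_dataset_counts
#' @export
tnbc_reference_crosstab <- function() {
  readr::read_tsv(
    system.file("extdata", "reference_crosstab.tsv", package = "tnbcsubtyper"),
    col_types = readr::cols(
      lehmann_subtype = "c", study_subtype = "c", percent = "d"
    ),
    progress = FALSE
  )
}
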