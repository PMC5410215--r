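#' Simulation configuration for synthetic multi-dataset cohorts
#'
#' Describes a multi-dataset breast-cancer cohort with bimodal receptor-probe
#' distributions, latent TNBC subtype structure (blocks of up- and
#' down-regulated marker probes), per-dataset additive location shifts and
#' Gaussian probe noise. Defaults emulate a Taiwanese-arm-sized compilation:
#' 3 datasets x 155 samples = 465 samples, per-marker positive fraction 0.36
#' so that roughly a quarter of samples are triple negative, and five latent
#' subtypes.
#'
#' @param n_datasets Number of datasets (batches).
#' @param samples_per_dataset Samples per dataset.
#' @param n_probes Number of non-receptor probes (marker blocks are carved out
#'   of these; three receptor probe rows are added on top).
#' @param receptor_mixture Per-marker two-component parameters: a named list
#'   (ER, PR, HER2), each a numeric vector with elements `mu_neg`, `sd_neg`,
#'   `mu_pos`, `sd_pos`, `positive_fraction` (log2 units).
#' @param n_subtypes Number of latent TNBC subtypes.
#' @param markers_per_subtype Marker probes planted per subtype (split roughly
#'   half up-, half down-regulated).
#' @param marker_effect Log2 shift added to a subtype's up-markers in member
#'   samples (and subtracted for down-markers).
#' @param noise_sd SD of the Gaussian probe noise (log2 units).
#' @param batch_shift_sd SD of the per-dataset additive shift applied to all
#'   probes (log2 units).
#' @param subtype_probs Optional probability vector over subtypes (defaults to
#'   uniform); allows unbalanced subtype proportions.
#' @param probes Receptor probe IDs, as from [marker_probes()].
#' @param seed Integer seed; generation is deterministic given the config.
#' @return A list of class `tnbc_sim_config`.
#' @export
sim_config <- function(n_datasets = 3,
                       samples_per_dataset = 155,
                       n_probes = 1000,
                       receptor_mixture = default_receptor_mixture(),
                       n_subtypes = 5,
                       markers_per_subtype = 10,
                       marker_effect = 2,
                       noise_sd = 0.5,
                       batch_shift_sd = 0.5,
                       subtype_probs = NULL,
                       probes = marker_probes(),
                       seed = 1L) {
  cfg <- list(
    n_datasets = as.integer(n_datasets),
    samples_per_dataset = as.integer(samples_per_dataset),
    n_probes = as.integer(n_probes),
    receptor_mixture = receptor_mixture,
    n_subtypes = as.integer(n_subtypes),
    markers_per_subtype = as.integer(markers_per_subtype),
    marker_effect = marker_effect,
    noise_sd = noise_sd,
    batch_shift_sd = batch_shift_sd,
    subtype_probs = subtype_probs,
    probes = probes,
    seed = as.integer(seed)
  )
  class(cfg) <- "tnbc_sim_config"
  validate_sim_config(cfg)
  cfg
}

default_receptor_mixture <- function() {
  list(
    ER   = c(mu_neg = 6.0, sd_neg = 1.0, mu_pos = 10.5, sd_pos = 1.0, positive_fraction = 0.36),
    PR   = c(mu_neg = 5.5, sd_neg = 1.0, mu_pos = 10.0, sd_pos = 1.0, positive_fraction = 0.36),
    HER2 = c(mu_neg = 7.0, sd_neg = 1.0, mu_pos = 11.5, sd_pos = 1.0, positive_fraction = 0.36)
  )
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_datasets < 1 || samples_per_dataset < 1 || n_probes < 1) {
      rlang::abort("n_datasets, samples_per_dataset, n_probes must be positive.")
    }
    if (!setequal(names(receptor_mixture), c("ER", "PR", "HER2"))) {
      rlang::abort("receptor_mixture must name exactly ER, PR, HER2.")
    }
    for (mk in names(receptor_mixture)) {
      p <- receptor_mixture[[mk]]
      need <- c("mu_neg", "sd_neg", "mu_pos", "sd_pos", "positive_fraction")
      if (!all(need %in% names(p))) {
        rlang::abort(sprintf("receptor_mixture$%s must have %s.",
                             mk, paste(need, collapse = ", ")))
      }
      if (p[["mu_pos"]] <= p[["mu_neg"]]) {
        rlang::abort(sprintf("%s: mu_pos must exceed mu_neg.", mk))
      }
      if (p[["sd_neg"]] <= 0 || p[["sd_pos"]] <= 0) {
        rlang::abort(sprintf("%s: component sds must be positive.", mk))
      }
      pf <- p[["positive_fraction"]]
      if (pf <= 0 || pf >= 1) {
        rlang::abort(sprintf("%s: positive_fraction must be in (0,1).", mk))
      }
    }
    if (n_subtypes < 1 || markers_per_subtype < 1) {
      rlang::abort("n_subtypes and markers_per_subtype must be positive.")
    }
    if (n_subtypes * markers_per_subtype > n_probes) {
      rlang::abort("markers_per_subtype * n_subtypes must not exceed n_probes.")
    }
    if (noise_sd < 0 || batch_shift_sd < 0) {
      rlang::abort("noise_sd and batch_shift_sd must be non-negative.")
    }
    if (!is.null(subtype_probs)) {
      if (length(subtype_probs) != n_subtypes || any(subtype_probs < 0) ||
          sum(subtype_probs) <= 0) {
        rlang::abort("subtype_probs must be n_subtypes non-negative weights.")
      }
    }
  })
  invisible(cfg)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Draws, per sample and marker, a positive/negative receptor status, then the
#' receptor-probe value from the corresponding mixture component; samples
#' negative on all three markers are TNBC and receive a latent subtype. Each
#' subtype's up-markers are shifted by `+marker_effect` and its down-markers by
#' `-marker_effect` in member samples. A single per-dataset shift
#' `Normal(0, batch_shift_sd)` is added to all probes, and every non-receptor
#' probe gets `Normal(0, noise_sd)` noise around its own baseline. Output is
#' bit-reproducible given the config (including its seed).
#'
#' @param config A [sim_config()].
#' @return A list of class `tnbc_cohort` with elements `expr` (an expression
#'   table, see [expr_table()]) and `truth` (class `tnbc_truth`: `$samples`, a
#'   tibble with receptor statuses, TNBC flag and subtype; `$markers`, a
#'   `tnbc_signature` tibble of the planted per-subtype up/down marker probes).
#' @export
generate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  withr::local_seed(config$seed)

  nd <- config$n_datasets
  spd <- config$samples_per_dataset
  n <- nd * spd
  datasets <- sprintf("dataset%02d", seq_len(nd))
  batch <- rep(datasets, each = spd)
  sample_id <- sprintf("%s_s%03d", batch, rep(seq_len(spd), times = nd))

  # receptor status and probe values
  status <- sapply(c("ER", "PR", "HER2"), function(mk) {
    stats::rbinom(n, 1, config$receptor_mixture[[mk]][["positive_fraction"]]) == 1
  })
  receptor_vals <- vapply(c("ER", "PR", "HER2"), function(mk) {
    p <- config$receptor_mixture[[mk]]
    mu <- ifelse(status[, mk], p[["mu_pos"]], p[["mu_neg"]])
    sd <- ifelse(status[, mk], p[["sd_pos"]], p[["sd_neg"]])
    stats::rnorm(n, mu, sd)
  }, numeric(n))
  tnbc <- !status[, "ER"] & !status[, "PR"] & !status[, "HER2"]

  # subtype assignment for TNBC samples
  probs <- config$subtype_probs
  if (is.null(probs)) probs <- rep(1, config$n_subtypes)
  subtype <- rep(NA_character_, n)
  subtype_names <- sprintf("subtype%d", seq_len(config$n_subtypes))
  if (any(tnbc)) {
    subtype[tnbc] <- sample(subtype_names, sum(tnbc), replace = TRUE,
                            prob = probs / sum(probs))
  }

  # probe layout: markers first, then background
  n_up <- ceiling(config$markers_per_subtype / 2)
  n_dn <- config$markers_per_subtype - n_up
  markers <- purrr::map_dfr(seq_len(config$n_subtypes), function(s) {
    tibble::tibble(
      subtype = subtype_names[s],
      direction = c(rep("up", n_up), rep("down", n_dn)),
      gene = sprintf("%s_%s_%02d", subtype_names[s],
                     c(rep("up", n_up), rep("down", n_dn)),
                     c(seq_len(n_up), seq_len(n_dn)))
    )
  })
  n_marker_rows <- nrow(markers)
  n_bg <- config$n_probes - n_marker_rows
  probe_names <- c(markers$gene,
                   if (n_bg > 0) sprintf("bg_%04d", seq_len(n_bg)))

  baseline <- stats::rnorm(config$n_probes, mean = 7, sd = 1)
  vals <- matrix(baseline, nrow = config$n_probes, ncol = n)
  if (config$noise_sd > 0) {
    vals <- vals + matrix(stats::rnorm(config$n_probes * n, 0, config$noise_sd),
                          nrow = config$n_probes)
  }
  for (s in seq_len(config$n_subtypes)) {
    members <- which(!is.na(subtype) & subtype == subtype_names[s])
    if (length(members) == 0) next
    rows <- which(markers$subtype == subtype_names[s])
    up <- rows[markers$direction[rows] == "up"]
    dn <- rows[markers$direction[rows] == "down"]
    vals[up, members] <- vals[up, members] + config$marker_effect
    vals[dn, members] <- vals[dn, members] - config$marker_effect
  }
  dimnames(vals) <- list(probe_names, sample_id)

  full <- rbind(t(receptor_vals), vals)
  rownames(full) <- c(unname(config$probes[c("ER", "PR", "HER2")]), probe_names)
  colnames(full) <- sample_id

  if (config$batch_shift_sd > 0) {
    shifts <- stats::rnorm(nd, 0, config$batch_shift_sd)
    full <- full + matrix(rep(shifts, each = spd), nrow = nrow(full),
                          ncol = n, byrow = TRUE)
  }

  truth_samples <- tibble::tibble(
    sample_id = sample_id,
    batch = batch,
    er_positive = status[, "ER"],
    pr_positive = status[, "PR"],
    her2_positive = status[, "HER2"],
    tnbc = tnbc,
    subtype = subtype
  )
  class(markers) <- c("tnbc_signature", class(markers))
  truth <- structure(list(samples = truth_samples, markers = markers),
                     class = "tnbc_truth")
  structure(
    list(expr = expr_table(full, batch = stats::setNames(batch, sample_id)),
         truth = truth, config = config),
    class = "tnbc_cohort"
  )
}

#' Fraction of truly triple-negative samples in a ground truth
#'
#' @param truth A `tnbc_truth` (from [generate_cohort()]) or a data frame with
#'   a logical `tnbc` column.
#' @return The fraction of samples whose TNBC flag is set.
#' @export
truth_tnbc_fraction <- function(truth) {
  df <- if (inherits(truth, "tnbc_truth")) truth$samples else truth
  if (!is.data.frame(df) || !"tnbc" %in% names(df)) {
    rlang::abort("`truth` must have a logical `tnbc` column.")
  }
  if (nrow(df) == 0) rlang::abort("empty ground truth.")
  mean(df$tnbc)
}
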