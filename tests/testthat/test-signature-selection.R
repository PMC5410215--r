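toy_labeled_matrix <- function(seed = 1, n_probes = 20, n_per = 10,
                               n_groups = 3, effect = 2, noise = 0.5) {
  withr::with_seed(seed, {
    n <- n_per * n_groups
    m <- matrix(rnorm(n_probes * n, 7, noise), n_probes, n,
                dimnames = list(sprintf("p%02d", 1:n_probes),
                                sprintf("s%02d", 1:n)))
    grp <- rep(sprintf("g%d", 1:n_groups), each = n_per)
    # plant two up-markers and one down-marker for g1
    m[1, grp == "g1"] <- m[1, grp == "g1"] + effect
    m[2, grp == "g1"] <- m[2, grp == "g1"] + effect
    m[3, grp == "g1"] <- m[3, grp == "g1"] - effect
    list(x = expr_table(m),
         labels = tibble::tibble(sample_id = colnames(m), subtype = grp))
  })
}

test_that("per-probe statistics match a brute-force recomputation", {
  fx <- toy_labeled_matrix()
  st <- subtype_vs_rest_stats(fx$x, fx$labels, "g1")
  m <- expr_values(fx$x)
  in_grp <- fx$labels$sample_id[fx$labels$subtype == "g1"]
  rest <- setdiff(fx$labels$sample_id, in_grp)
  for (p in rownames(m)) {
    m1 <- mean(m[p, in_grp]); m2 <- mean(m[p, rest])
    expect_equal(st$fold_change[st$probe_id == p], 2^(m1 - m2))
    expect_equal(st$frac_above[st$probe_id == p], mean(m[p, in_grp] > m2))
    expect_equal(st$frac_below[st$probe_id == p], mean(m[p, in_grp] < m2))
    tt <- t.test(m[p, in_grp], m[p, rest])
    expect_equal(st$p_value[st$probe_id == p], tt$p.value, tolerance = 1e-12)
  }
})

test_that("degenerate probes: constants give FC 1, fraction 0, p 1; clean shifts give exact stats", {
  m <- matrix(5, 4, 12, dimnames = list(sprintf("p%d", 1:4),
                                        sprintf("s%02d", 1:12)))
  grp <- tibble::tibble(sample_id = colnames(m),
                        subtype = rep(c("a", "b"), each = 6))
  m[2, grp$subtype == "a"] <- 6  # one log2 unit above rest, zero variance
  st <- subtype_vs_rest_stats(expr_table(m), grp, "a")
  expect_equal(st$fold_change[1], 1)
  expect_equal(st$frac_above[1], 0)
  expect_equal(st$p_value[1], 1)
  expect_equal(st$fold_change[2], 2)
  expect_equal(st$frac_above[2], 1)
  expect_equal(st$p_value[2], 0)

  expect_error(subtype_vs_rest_stats(expr_table(m), grp[1:8, ], "b"), ">= 3")
})

test_that("three-criterion selection recovers planted markers with high precision/recall", {
  co <- planted_cohort(seed = 41)
  norm <- suppressMessages(normalize_per_dataset(co$expr))
  x <- tnbc_submatrix(co, norm)
  truth <- co$truth$samples
  labels <- tibble::tibble(
    sample_id = sample_ids(x),
    subtype = truth$subtype[match(sample_ids(x), truth$sample_id)]
  )
  stats <- purrr::map_dfr(sort(unique(labels$subtype)), function(st)
    subtype_vs_rest_stats(x, labels, st))
  sel <- select_signature(stats)
  planted <- co$truth$markers
  key <- function(d) paste(d$subtype, d$direction, d$gene)
  tp <- length(intersect(key(sel), key(planted)))
  precision <- tp / nrow(sel)
  recall <- tp / nrow(planted)
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.9)
})

test_that("thresholds are strict and selection is monotone in each threshold", {
  stats <- tibble::tibble(
    probe_id = c("a", "b", "c", "d"),
    subtype = "g1",
    mean_subtype = 0, mean_rest = 0,
    log2_fc = log2(c(1.74, 2.5, 0.4, 3)),
    fold_change = c(1.74, 2.5, 0.4, 3),
    frac_above = c(1, 1, 0, 0.8),
    frac_below = c(0, 0, 1, 0.1),
    p_value = c(1e-9, 1e-9, 1e-9, 1e-9)
  )
  sel <- select_signature(stats)
  # FC 1.74 misses the strict 1.75 cut; fraction exactly 0.8 misses 0.8 cut
  expect_false("a" %in% sel$gene)
  expect_false("d" %in% sel$gene)
  expect_setequal(sel$gene[sel$direction == "up"], "b")
  expect_setequal(sel$gene[sel$direction == "down"], "c")

  fx <- toy_labeled_matrix(seed = 5)
  st <- subtype_vs_rest_stats(fx$x, fx$labels, "g1")
  base <- select_signature(st, fc_up = 1.75, fc_down = 0.5,
                           min_fraction = 0.8, max_p = 1e-4)
  looser <- list(
    select_signature(st, fc_up = 1.2, fc_down = 0.5, min_fraction = 0.8, max_p = 1e-4),
    select_signature(st, fc_up = 1.75, fc_down = 0.8, min_fraction = 0.8, max_p = 1e-4),
    select_signature(st, fc_up = 1.75, fc_down = 0.5, min_fraction = 0.5, max_p = 1e-4),
    select_signature(st, fc_up = 1.75, fc_down = 0.5, min_fraction = 0.8, max_p = 1e-2)
  )
  key <- function(d) paste(d$direction, d$probe_id)
  for (lo in looser) expect_true(all(key(base) %in% key(lo)))

  expect_error(select_signature(st, fc_up = 0.9), "fc_up")
})

test_that("probe-to-gene collapse keeps only the strongest probe per gene", {
  stats <- tibble::tibble(
    probe_id = c("p1", "p2", "p3"),
    subtype = "g1",
    mean_subtype = 0, mean_rest = 0,
    log2_fc = c(1.2, 2.0, 1.5),
    fold_change = 2^c(1.2, 2.0, 1.5),
    frac_above = 1, frac_below = 0,
    p_value = 1e-9
  )
  gm <- tibble::tibble(probe_id = c("p1", "p2", "p3"),
                       gene = c("G", "G", "H"))
  sel <- select_signature(stats, gene_map = gm)
  expect_setequal(sel$probe_id, c("p2", "p3"))
})

test_that("label-permutation null yields fewer than one selected probe per 1000 on average", {
  n <- 60
  m <- withr::with_seed(71, matrix(rnorm(1000 * n, 7, 1), 1000, n,
                                   dimnames = list(sprintf("p%04d", 1:1000),
                                                   sprintf("s%02d", 1:n))))
  x <- expr_table(m)
  counts <- vapply(1:20, function(i) {
    labels <- withr::with_seed(400 + i, tibble::tibble(
      sample_id = colnames(m),
      subtype = sample(rep(c("a", "b", "c"), each = n / 3))
    ))
    st <- subtype_vs_rest_stats(x, labels, "a")
    nrow(select_signature(st))
  }, numeric(1))
  expect_lt(mean(counts), 1)
})
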