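#' Adjusted Rand index between two labelings
#'
#' Hubert-Arabie adjusted Rand index: pair-counting agreement between two
#' partitions, corrected for chance (1 = identical partitions, ~0 = random).
#'
#' @param a,b Label vectors over the same samples (order-aligned).
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) rlang::abort("labelings differ in length.")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
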