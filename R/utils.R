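#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#' Used throughout the test suite to score recovery of planted modules and
#' subtypes.
#'
#' @param a,b label vectors of equal length (any atomic type; `NA`s must be
#'   removed by the caller).
#' @return The adjusted Rand index, 1 for identical partitions (up to label
#'   renaming), about 0 for independent ones.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  if (anyNA(a) || anyNA(b)) stop("remove NA labels before computing ARI")
  tab <- table(a, b)
  n <- sum(tab)
  if (n < 2) return(1)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# All permutations of 1..n as a list of integer vectors (n <= 8 in practice).
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1L)
    out <- c(out, lapply(rest, function(p) c(i, setdiff(seq_len(n), i)[p])))
  }
  out
}

# Run expr with a local seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}
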