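#' @keywords internal
"_PACKAGE"

# Shared small helpers. Kept deliberately free of dependencies beyond base R.

geometric_mean <- function(x) exp(mean(log(x)))

#' Adjusted Rand index between two labelings
#'
#' Agreement between two partitions of the same genes, corrected for chance.
#' Used throughout the tests to score recovery of planted module structure.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A number in (-1, 1]; 1 means identical partitions up to label names.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  maximum <- (sum_i + sum_j) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

# Deterministic per-region / per-block seed derivation from one root seed.
# Linear congruential step keeps everything below 2^31.
derive_seed <- function(root_seed, index) {
  as.integer((as.numeric(root_seed) * 48271 + 7919 * as.numeric(index)) %% 2147483647)
}

row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single number in [0, 1]", name), call. = FALSE)
}
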