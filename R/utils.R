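#' @keywords internal
"_PACKAGE"

# geometric mean of a positive vector
geomean <- function(x) exp(mean(log(x)))

stop_ic <- function(...) stop(sprintf(...), call. = FALSE)

warn_ic <- function(...) warning(sprintf(...), call. = FALSE)

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples,
#' used throughout to measure recovery of planted class structure.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return a single number in [-1, 1]; 1 means identical partitions up to
#'   relabeling, 0 is the expectation under independent random partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

# deterministic per-stage seed derived from a master seed; keeps stages
# decoupled while the whole run is reproducible from one integer
derive_seed <- function(master, offset) {
  (as.integer(master) + 1009L * as.integer(offset)) %% 2147483647L
}
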