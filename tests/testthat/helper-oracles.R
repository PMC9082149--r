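# Independent oracles used across tests.

# Exhaustive DTW: enumerate every admissible monotone path from (1,1) to
# (m,m) recursively and return the minimum summed cost. Deliberately not a
# dynamic program so it stays independent of the implementation.
dtw_brute <- function(a, b, index_cost = TRUE) {
  m <- length(a)
  n <- length(b)
  local_cost <- function(i, j) {
    di <- if (index_cost) (i - j)^2 else 0
    sqrt(di + (a[i] - b[j])^2)
  }
  recurse <- function(i, j) {
    c0 <- local_cost(i, j)
    if (i == m && j == n) return(c0)
    best <- Inf
    if (i < m && j < n) best <- min(best, recurse(i + 1, j + 1))
    if (i < m) best <- min(best, recurse(i + 1, j))
    if (j < n) best <- min(best, recurse(i, j + 1))
    c0 + best
  }
  recurse(1, 1)
}

# Direct evaluation of the product-moment correlation, written as the
# textbook ratio (not via stats::cor) for use as an oracle.
pearson_direct <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    (sqrt(sum((x - mean(x))^2)) * sqrt(sum((y - mean(y))^2)))
}

# Greedy one-to-one peak matching within a tolerance (samples); returns
# sensitivity and precision.
match_peaks <- function(truth, detected, tol) {
  used <- logical(length(detected))
  hits <- 0L
  for (t in truth) {
    ok <- which(!used & abs(detected - t) <= tol)
    if (length(ok) > 0) {
      used[ok[which.min(abs(detected[ok] - t))]] <- TRUE
      hits <- hits + 1L
    }
  }
  list(sensitivity = hits / length(truth),
       precision = if (length(detected) == 0) NA_real_
                   else sum(used) / length(detected))
}

# RMS helper for filter-gain checks
rms <- function(x) sqrt(mean(x^2))
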