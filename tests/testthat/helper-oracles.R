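# Independent oracles used by the tests. These are written directly from the
# definition of the symmetric P = 1 (slope-constrained) step pattern and do
# not share code with the package implementation.

# Exhaustive enumeration of all admissible warping paths for small inputs.
# A path is a sequence of composite moves from (1,1) to (N,M):
#   (i,j) -> (i+1,j+1)           cost 2*delta(i+1,j+1)
#   (i,j) -> (i+1,j+2)           cost 2*delta(i+1,j+1) + delta(i+1,j+2)
#   (i,j) -> (i+2,j+1)           cost 2*delta(i+1,j+1) + delta(i+2,j+1)
# total cost = delta(1,1) + sum of move costs.
dtw_p1_enumerate <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 1)
  if (is.null(dim(b))) b <- matrix(b, ncol = 1)
  delta <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  n <- nrow(a); m <- nrow(b)
  best <- Inf
  rec <- function(i, j, acc) {
    if (acc >= best) return(invisible(NULL))
    if (i == n && j == m) { best <<- min(best, acc); return(invisible(NULL)) }
    if (i < n && j < m) rec(i + 1, j + 1, acc + 2 * delta(i + 1, j + 1))
    if (i < n && j + 2 <= m)
      rec(i + 1, j + 2, acc + 2 * delta(i + 1, j + 1) + delta(i + 1, j + 2))
    if (i + 2 <= n && j < m)
      rec(i + 2, j + 1, acc + 2 * delta(i + 1, j + 1) + delta(i + 2, j + 1))
    invisible(NULL)
  }
  rec(1, 1, delta(1, 1))
  best
}

# Top-down memoized recursion on the same step set (handles larger inputs).
dtw_p1_memo <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 1)
  if (is.null(dim(b))) b <- matrix(b, ncol = 1)
  n <- nrow(a); m <- nrow(b)
  delta <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  memo <- matrix(NA_real_, n, m)
  g <- function(i, j) {
    if (i < 1 || j < 1) return(Inf)
    if (i == 1 && j == 1) return(delta(1, 1))
    if (i == 1 || j == 1) return(Inf)
    if (!is.na(memo[i, j])) return(memo[i, j])
    v <- min(g(i - 1, j - 1) + 2 * delta(i, j),
             g(i - 1, j - 2) + 2 * delta(i, j - 1) + delta(i, j),
             g(i - 2, j - 1) + 2 * delta(i - 1, j) + delta(i, j))
    memo[i, j] <<- v
    v
  }
  g(n, m)
}

# Random 3-D trajectory (correlated steps so costs are non-trivial).
random_traj <- function(n, drift = 0.3) {
  steps <- matrix(rnorm(3 * n, sd = 1), ncol = 3)
  steps[, 1] <- steps[, 1] + drift
  apply(rbind(runif(3, -5, 5), steps), 2, cumsum)
}
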