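#' Permutation test for sister-trajectory similarity
#'
#' Pools the log DTW distances of uni-fated and bipotent sister pairs,
#' reassigns them at random to the two groups (preserving group sizes), and
#' compares the observed difference in group means,
#' `mean(bipotent) - mean(uni)`, with the permutation null. The alternative
#' is one-sided: uni-fated sisters have smaller log DTW, i.e. the observed
#' difference is larger than under the null. The p-value uses the add-one
#' correction `p = (1 + #{null >= observed}) / (n_perm + 1)`. With
#' `exact = TRUE` (or automatically when both groups have at most
#' `exact_max` values) all label assignments are enumerated instead, and
#' `p = #{assignments with diff >= observed} / #assignments`.
#'
#' @param uni,bi numeric vectors of log DTW distances for same-fate and
#'   distinct-fate pairs.
#' @param n_perm number of random permutations (default 100000).
#' @param seed optional integer seed for reproducibility.
#' @param exact force (or forbid, `FALSE`) exhaustive enumeration;
#'   default `NULL` = enumerate when `choose(n, n_uni) <= 200000`.
#' @return Object of class `permutation_test`: `observed_diff`, `p_value`,
#'   `null_mean`, `null_sd`, `null_quantiles`, `n_perm` (or the number of
#'   enumerated assignments), `exact`, `seed`.
#' @export
permutation_test <- function(uni, bi, n_perm = 100000L, seed = NULL,
                             exact = NULL) {
  if (!length(uni) || !length(bi))
    stop_data("permutation test needs both groups non-empty")
  if (n_perm < 1L) stop_data("config error: n_perm must be >= 1")
  pool <- c(uni, bi)
  n_u <- length(uni); n <- length(pool)
  observed <- mean(bi) - mean(uni)
  n_comb <- choose(n, n_u)
  if (is.null(exact)) exact <- n_comb <= 2e5
  tot <- sum(pool)
  # diff = mean(bi) - mean(uni) is a monotone function of sum(uni):
  # diff = (tot - s)/ (n - n_u) - s / n_u
  diff_from_sum_uni <- function(s) (tot - s) / (n - n_u) - s / n_u
  if (exact) {
    sums <- utils::combn(pool, n_u, sum)
    null <- diff_from_sum_uni(sums)
    p <- mean(null >= observed - 1e-12)
    n_used <- length(null)
  } else {
    if (!is.null(seed)) set.seed(seed)
    null <- vapply(seq_len(n_perm), function(k)
      diff_from_sum_uni(sum(pool[sample.int(n, n_u)])), 0)
    p <- (1 + sum(null >= observed - 1e-12)) / (n_perm + 1)
    n_used <- n_perm
  }
  structure(list(observed_diff = observed, p_value = p,
                 null_mean = mean(null), null_sd = stats::sd(null),
                 null_quantiles = stats::quantile(null,
                                                  c(0.025, 0.5, 0.975)),
                 n_perm = n_used, exact = exact, seed = seed),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("<permutation_test> observed mean diff (bi - uni) = %.4g\n",
              x$observed_diff))
  cat(sprintf("  one-sided p = %.3g (%s, %d %s)\n", x$p_value,
              if (x$exact) "exact enumeration" else "Monte Carlo",
              x$n_perm, if (x$exact) "assignments" else "permutations"))
  invisible(x)
}

#' Mann-Whitney rank-sum test
#'
#' Standard two-sided Mann-Whitney U. For `min(n) <= exact_max` and no more
#' than `2e5` label assignments, the p-value is computed by exhaustive
#' enumeration of group assignments of the ranks (valid under ties);
#' otherwise the normal approximation with tie correction and continuity
#' correction from [stats::wilcox.test()] is used.
#'
#' @param a,b numeric vectors.
#' @param exact_max largest `min(n)` for which enumeration is attempted
#'   (default 8).
#' @return List with `U` (statistic for group `a`), `p_value`, `method`.
#' @export
rank_sum_test <- function(a, b, exact_max = 8L) {
  if (!length(a) || !length(b)) stop_data("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (min(n1, n2) <= exact_max && choose(n1 + n2, n1) <= 2e5) {
    mu <- n1 * n2 / 2
    sums <- utils::combn(r, n1, sum)
    Us <- sums - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-12)
    list(U = U, p_value = p, method = "exact enumeration")
  } else {
    wt <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    list(U = unname(wt$statistic), p_value = wt$p.value,
         method = "normal approximation with tie correction")
  }
}
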