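#' @keywords internal
"_PACKAGE"

# Small shared helpers. Positions are always 3-vectors in micrometres; time is
# minutes on the movie's local clock unless a function says "aligned".

vec_norm <- function(v) sqrt(sum(v^2))

# Row-wise Euclidean norm of an n x 3 matrix.
row_norms <- function(m) sqrt(rowSums(m^2))

# Path length of an ordered n x 3 position matrix (sum of step lengths).
path_length <- function(pos) {
  if (nrow(pos) < 2L) return(0)
  sum(row_norms(diff(pos)))
}

unit <- function(v) {
  n <- vec_norm(v)
  if (n == 0) return(v)
  v / n
}

# Uniform random unit 3-vectors, n x 3.
random_units <- function(n) {
  m <- matrix(stats::rnorm(3L * n), ncol = 3L)
  m / pmax(row_norms(m), .Machine$double.eps)
}

stop_data <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Linear interpolation of a cell track at arbitrary times. pos is n x 3 with
# strictly increasing times t; query times outside [t_1, t_n] give NA rows.
interp_positions <- function(t, pos, t_out) {
  out <- matrix(NA_real_, nrow = length(t_out), ncol = 3L)
  ok <- t_out >= t[1L] & t_out <= t[length(t)]
  if (any(ok)) {
    for (k in 1:3) {
      out[ok, k] <- stats::approx(t, pos[, k], xout = t_out[ok], rule = 1)$y
    }
  }
  out
}
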