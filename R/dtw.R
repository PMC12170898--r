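#' Slope-constrained dynamic time warping of two trajectories
#'
#' Computes the symmetric, slope-constrained (Sakoe-Chiba P = 1) DTW
#' distance between two 3-D trajectories, the step pattern known as
#' `symmetricP1`. With local Euclidean distance
#' \eqn{\delta(i,j) = \|a_i - b_j\|}, the dynamic programme is
#' \deqn{g(1,1) = \delta(1,1)}
#' \deqn{g(i,j) = \min\{\, g(i-1,j-2) + 2\delta(i,j-1) + \delta(i,j),\;
#'   g(i-1,j-1) + 2\delta(i,j),\; g(i-2,j-1) + 2\delta(i-1,j) + \delta(i,j) \,\}}
#' so each diagonal move may be preceded by at most one horizontal or
#' vertical move (slope window P = 1). Cells unreachable under the
#' constraint stay at +Inf. The warping path is recovered by backtracking
#' with a deterministic tie-break: diagonal first, then the column-advancing
#' composite step, then the row-advancing one.
#'
#' @param a,b numeric matrices (rows = time points, columns = coordinates;
#'   a vector is treated as a 1-column matrix). Both need at least 2 rows.
#' @param normalize also report cost / (N + M)?
#' @return Object of class `dtw_alignment`: list with `cumulative_cost`,
#'   `normalized_cost` (or `NA` unless `normalize`), `path` (two-column
#'   index matrix from (1,1) to (N,M)), `step_costs` (local cost added by
#'   each path step, whose sum plus \eqn{\delta(1,1)} is the cumulative
#'   cost), `N`, `M`.
#' @export
dtw_distance <- function(a, b, normalize = FALSE) {
  a <- as_traj(a); b <- as_traj(b)
  n <- nrow(a); m <- nrow(b)
  if (n < 2L || m < 2L)
    stop_data("dtw input error: both trajectories need >= 2 points")
  if (ncol(a) != ncol(b))
    stop_data("dtw input error: dimension mismatch (%d vs %d)", ncol(a), ncol(b))
  if (m > 2L * n - 1L || n > 2L * m - 1L)
    stop_data("infeasible warp: lengths %d and %d violate the P = 1 slope constraint",
              n, m)
  # full local cost matrix delta[i, j]
  d <- local_cost_matrix(a, b)
  g <- matrix(Inf, n, m)
  g[1L, 1L] <- d[1L, 1L]
  # row i depends only on rows i-1, i-2 => vectorise over j
  if (n >= 2L) {
    for (i in 2:n) {
      j <- 2:m
      diag_ <- g[i - 1L, j - 1L] + 2 * d[i, j]
      horiz <- if (m >= 3L)
        c(Inf, g[i - 1L, seq_len(m - 2L)] + 2 * d[i, j[-1L] - 1L] + d[i, j[-1L]])
      else Inf
      vert <- if (i >= 3L)
        g[i - 2L, j - 1L] + 2 * d[i - 1L, j] + d[i, j]
      else rep(Inf, length(j))
      g[i, j] <- pmin(diag_, horiz, vert)
    }
  }
  cost <- g[n, m]
  # backtrack
  path <- matrix(NA_integer_, n + m, 2L)
  steps <- numeric(n + m)
  k <- 1L
  i <- n; j <- m
  path[k, ] <- c(i, j)
  while (!(i == 1L && j == 1L)) {
    cand_cost <- c(
      if (i >= 2L && j >= 2L) g[i - 1L, j - 1L] + 2 * d[i, j] else Inf,
      if (i >= 2L && j >= 3L) g[i - 1L, j - 2L] + 2 * d[i, j - 1L] + d[i, j] else Inf,
      if (i >= 3L && j >= 2L) g[i - 2L, j - 1L] + 2 * d[i - 1L, j] + d[i, j] else Inf)
    pick <- which(abs(cand_cost - g[i, j]) <= 1e-9 * max(1, abs(g[i, j])))[1L]
    if (is.na(pick)) pick <- which.min(cand_cost)  # numerical safety
    steps[k] <- g[i, j] - cand_cost_base(g, i, j, pick)
    if (pick == 1L) { i <- i - 1L; j <- j - 1L }
    else if (pick == 2L) { i <- i - 1L; j <- j - 2L }
    else { i <- i - 2L; j <- j - 1L }
    k <- k + 1L
    path[k, ] <- c(i, j)
  }
  path <- path[k:1, , drop = FALSE]
  steps <- rev(steps[seq_len(k - 1L)])
  structure(list(cumulative_cost = cost,
                 normalized_cost = if (normalize) cost / (n + m) else NA_real_,
                 path = path, step_costs = steps, N = n, M = m),
            class = "dtw_alignment")
}

as_traj <- function(x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = 1L)
  storage.mode(x) <- "double"
  x
}

local_cost_matrix <- function(a, b) {
  n <- nrow(a); m <- nrow(b)
  d <- matrix(0, n, m)
  for (k in seq_len(ncol(a)))
    d <- d + outer(a[, k], b[, k], `-`)^2
  sqrt(d)
}

# cost of the predecessor cell of step `pick` taken from (i, j)
cand_cost_base <- function(g, i, j, pick) {
  if (pick == 1L) g[i - 1L, j - 1L]
  else if (pick == 2L) g[i - 1L, j - 2L]
  else g[i - 2L, j - 1L]
}

#' @export
print.dtw_alignment <- function(x, ...) {
  cat(sprintf("<dtw_alignment> N=%d M=%d cumulative cost %.6g", x$N, x$M,
              x$cumulative_cost))
  if (!is.na(x$normalized_cost))
    cat(sprintf(" (normalized %.6g)", x$normalized_cost))
  cat(sprintf(", %d path steps\n", nrow(x$path) - 1L))
  invisible(x)
}

#' Sister/cousin DTW table for a lineage forest
#'
#' For every division in generations `generations`, pairs the two daughters
#' (sisters) and, at the second generation, also the four cross pairs of
#' granddaughters (cousins: D11-D21, D11-D22, D12-D21, D12-D22).
#' Trajectories run from the first frame after the mother's division to the
#' last time point before the first cell of the pair divides again, further
#' truncated at `end_of_migration` (aligned minutes). Each pair is assigned
#' a fate category from the two cells' determined fates:
#' `Uni` (same cardiac fate, no ExEm), `UniExEm` (both ExEm), `Bi` (distinct
#' fates, no ExEm), `BiExEm` (distinct fates, at least one ExEm); pairs with
#' an undetermined or mixed side get `NA`.
#'
#' @param forest a `lineage_forest` (or list of them) with leaf fates.
#' @param generations integer subset of `c(1, 2)`: which daughter
#'   generations to pair.
#' @param end_of_migration aligned minutes at which trajectories stop
#'   (default `Inf` = whole track).
#' @param cadence keep every `cadence`-th frame of each trajectory
#'   (default 1 = the full 2-min sampling).
#' @param keep_alignments also return the `dtw_alignment` objects (needed by
#'   [mean_dtw_curve()]).
#' @return data.frame with one row per pair: ids, `relation`
#'   (sisters/cousins), `generation`, `category`, `dtw`, `log_dtw`,
#'   `n_steps`; alignments in `attr(, "alignments")` if requested. Pairs
#'   whose shared interval is shorter than 2 frames are skipped.
#' @export
pair_dtw_table <- function(forest, generations = c(1L, 2L),
                           end_of_migration = Inf, cadence = 1L,
                           keep_alignments = FALSE) {
  if (inherits(forest, "lineage_forest")) forest <- list(forest)
  rows <- list(); aligns <- list()
  for (f in forest) {
    fate <- derived_fates(f)
    off <- f$meta$alignment_offset_min
    labs <- stats::setNames(f$cells$generation_label, f$cells$cell_id)
    traj <- function(id, t_stop) {
      s <- cell_spots(f, id)
      s <- s[s$t_min + off <= t_stop, , drop = FALSE]
      if (cadence > 1L) s <- s[seq(1L, nrow(s), by = cadence), , drop = FALSE]
      s
    }
    add_pair <- function(id1, id2, relation) {
      gen <- generation_of(labs[[id1]])
      s1 <- cell_spots(f, id1); s2 <- cell_spots(f, id2)
      # last time before the first member of the pair re-divides
      redivide <- suppressWarnings(min(vapply(c(id1, id2), function(id) {
        kids <- forest_children(f, id)
        if (length(kids)) s <- cell_spots(f, id)$t_min else return(Inf)
        max(s)
      }, 0)))
      t_stop <- min(redivide + off, end_of_migration)
      s1 <- traj(id1, t_stop); s2 <- traj(id2, t_stop)
      if (nrow(s1) < 2L || nrow(s2) < 2L) return(invisible(NULL))
      n <- nrow(s1); m <- nrow(s2)
      if (m > 2L * n - 1L || n > 2L * m - 1L) return(invisible(NULL))
      al <- dtw_distance(cell_pos_matrix(s1), cell_pos_matrix(s2))
      f1 <- fate[[id1]]; f2 <- fate[[id2]]
      rows[[length(rows) + 1L]] <<- data.frame(
        movie_id = f$movie_id, cell_a = id1, cell_b = id2,
        relation = relation, generation = gen,
        category = pair_category(f1, f2),
        fate_a = f1, fate_b = f2,
        dtw = al$cumulative_cost,
        log_dtw = if (al$cumulative_cost > 0) log(al$cumulative_cost) else NA_real_,
        n_steps = nrow(al$path) - 1L, stringsAsFactors = FALSE)
      if (keep_alignments) aligns[[length(aligns) + 1L]] <<- al
      invisible(NULL)
    }
    for (cid in f$cells$cell_id) {
      kids <- forest_children(f, cid)
      if (length(kids) != 2L) next
      kids <- kids[order(labs[kids])]
      gen_kids <- generation_of(labs[[kids[1L]]])
      if (gen_kids %in% generations) add_pair(kids[1L], kids[2L], "sisters")
      # cousins: granddaughter cross pairs, evaluated once per grandmother
      if (generation_of(labs[[cid]]) == 0L && 2L %in% generations) {
        g1 <- forest_children(f, kids[1L]); g2 <- forest_children(f, kids[2L])
        if (length(g1) == 2L && length(g2) == 2L)
          for (u in g1) for (v in g2) add_pair(u, v, "cousins")
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(movie_id = character(0), cell_a = character(0),
                  cell_b = character(0), relation = character(0),
                  generation = integer(0), category = character(0),
                  fate_a = character(0), fate_b = character(0),
                  dtw = numeric(0), log_dtw = numeric(0),
                  n_steps = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (keep_alignments) attr(out, "alignments") <- aligns
  out
}

pair_category <- function(f1, f2) {
  if (any(c(f1, f2) %in% c("UNDETERMINED", "MIXED")) || is.na(f1) || is.na(f2))
    return(NA_character_)
  exem <- c(f1, f2) == "EXEM"
  if (f1 == f2) {
    if (all(exem)) "UniExEm" else "Uni"
  } else {
    if (any(exem)) "BiExEm" else "Bi"
  }
}

#' Mean cumulative DTW cost over the first warping-path steps
#'
#' For each pair's alignment, the cumulative cost after path step k (the
#' initial cell \eqn{\delta(1,1)} plus the first k step costs); the curve is
#' the mean over pairs at each k = 1..`n_steps`, with pairs dropping out
#' beyond their own path length. The alternative reading by trajectory
#' frame rather than path step is available via `by = "frame"`, which uses
#' the cumulative cost at the last path step whose row index is <= k.
#'
#' @param alignments list of `dtw_alignment` objects (e.g.
#'   `attr(pair_dtw_table(..., keep_alignments = TRUE), "alignments")`).
#' @param n_steps number of steps (default 40).
#' @param by `"step"` (warping-path steps, default) or `"frame"`.
#' @return data.frame with `step`, `mean`, `se`, `n`.
#' @export
mean_dtw_curve <- function(alignments, n_steps = 40L, by = c("step", "frame")) {
  by <- match.arg(by)
  stopifnot(length(alignments) >= 1L)
  cum <- lapply(alignments, function(al) {
    # cumulative cost after each path step; the offset is delta(1,1)
    cc <- cumsum(al$step_costs) + (al$cumulative_cost - sum(al$step_costs))
    if (by == "step") cc
    else {
      i_rows <- al$path[-1L, 1L]
      vapply(seq_len(al$N - 1L), function(k) {
        w <- which(i_rows <= k + 1L)
        if (length(w)) cc[max(w)] else NA_real_
      }, 0)
    }
  })
  out <- data.frame(step = seq_len(n_steps), mean = NA_real_, se = NA_real_,
                    n = 0L)
  for (k in seq_len(n_steps)) {
    v <- unlist(lapply(cum, function(cc) if (length(cc) >= k) cc[k] else NULL))
    if (length(v)) {
      out$mean[k] <- mean(v)
      out$se[k] <- if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0
      out$n[k] <- length(v)
    }
  }
  out
}

#' Count divergent uni-fated and convergent bipotent pairs by log DTW
#'
#' Splits the second-generation pair table at a log-DTW threshold:
#' uni-fated pairs above it migrated divergently despite sharing a fate;
#' bipotent pairs below it stayed similar despite fate divergence. Pairs
#' with zero cost (undefined log) are excluded with a warning.
#'
#' @param pair_table output of [pair_dtw_table()].
#' @param threshold log-DTW cut (default 4.5).
#' @param generation which generation to examine (default 2).
#' @return Named list with counts `uni_above`, `uni_total`, `bi_below`,
#'   `bi_total`.
#' @export
classify_by_logdtw <- function(pair_table, threshold = 4.5, generation = 2L) {
  tb <- pair_table[pair_table$generation == generation &
                     !is.na(pair_table$category), , drop = FALSE]
  if (any(is.na(tb$log_dtw))) {
    warning(sprintf("excluding %d pair(s) with zero DTW cost (log undefined)",
                    sum(is.na(tb$log_dtw))), call. = FALSE)
    tb <- tb[!is.na(tb$log_dtw), , drop = FALSE]
  }
  uni <- tb[tb$category %in% c("Uni", "UniExEm"), , drop = FALSE]
  bi <- tb[tb$category %in% c("Bi", "BiExEm"), , drop = FALSE]
  list(uni_above = sum(uni$log_dtw > threshold), uni_total = nrow(uni),
       bi_below = sum(bi$log_dtw < threshold), bi_total = nrow(bi))
}
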