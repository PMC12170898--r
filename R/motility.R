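#' Mean speed per cell in aligned 5-hour intervals
#'
#' The aligned timeline is divided into fixed bins (default 5 h); within
#' each bin a cell's speed is its path length divided by its tracked time
#' in the bin (step assigned to the bin containing its starting time).
#' Records with less than `min_duration_min` of track in a bin are dropped.
#'
#' @param forest a `lineage_forest` or list of them.
#' @param bin_hours bin width in hours (default 5).
#' @param min_duration_min minimum time in bin (default 40).
#' @return data.frame with `movie_id`, `cell_id`, `fate`, `bin` (index,
#'   1 = first 5 h), `bin_start_min`, `speed_um_min`, `duration_in_bin_min`.
#' @export
interval_speed <- function(forest, bin_hours = 5, min_duration_min = 40) {
  if (inherits(forest, "lineage_forest")) forest <- list(forest)
  bw <- bin_hours * 60
  rows <- list()
  for (f in forest) {
    off <- f$meta$alignment_offset_min
    fate <- derived_fates(f)
    for (cid in f$cells$cell_id) {
      s <- cell_spots(f, cid)
      if (nrow(s) < 2L) next
      pos <- cell_pos_matrix(s)
      step_len <- row_norms(diff(pos))
      step_dt <- diff(s$t_min)
      step_t0 <- s$t_min[-nrow(s)] + off
      bin <- floor(step_t0 / bw)
      for (b in unique(bin)) {
        sel <- bin == b
        dur <- sum(step_dt[sel])
        if (dur < min_duration_min) next
        rows[[length(rows) + 1L]] <- data.frame(
          movie_id = f$movie_id, cell_id = cid, fate = unname(fate[cid]),
          bin = b + 1L, bin_start_min = b * bw,
          speed_um_min = sum(step_len[sel]) / dur,
          duration_in_bin_min = dur, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(movie_id = character(0), cell_id = character(0),
                  fate = character(0), bin = integer(0),
                  bin_start_min = numeric(0), speed_um_min = numeric(0),
                  duration_in_bin_min = numeric(0), stringsAsFactors = FALSE)
}

#' Windowed tortuosity of a cell track
#'
#' Tortuosity = straight-line distance / total path distance, computed in
#' consecutive windows (default 50 min) from the start of the cell life and
#' averaged; 1 means perfectly straight. The final partial window is kept
#' only if it lasts at least `partial_min` minutes. A stationary window
#' (zero path length) counts as straight (1). Cells with a cycle shorter
#' than `min_cycle_min` (default 3 h) are excluded (`NULL` return).
#'
#' @param forest a `lineage_forest`.
#' @param cell_id the cell to measure.
#' @param window_min window length (default 50).
#' @param min_cycle_min minimum cell-cycle length (default 180).
#' @param partial_min minimum length of the trailing partial window
#'   (default 25).
#' @return List with `cell_id`, `local_values`, `mean_tortuosity`, or
#'   `NULL` when the cell is excluded.
#' @export
tortuosity <- function(forest, cell_id, window_min = 50,
                       min_cycle_min = 180, partial_min = 25) {
  s <- cell_spots(forest, cell_id)
  if (nrow(s) < 2L) return(NULL)
  dur <- s$t_min[nrow(s)] - s$t_min[1L]
  if (dur < min_cycle_min) return(NULL)
  pos <- cell_pos_matrix(s)
  rel_t <- s$t_min - s$t_min[1L]
  n_win <- ceiling(dur / window_min)
  vals <- numeric(0)
  for (k in seq_len(n_win)) {
    w0 <- (k - 1L) * window_min; w1 <- k * window_min
    sel <- rel_t >= w0 & rel_t <= w1
    if (sum(sel) < 2L) next
    if (k == n_win && (dur - w0) < partial_min) next
    p <- pos[sel, , drop = FALSE]
    total <- path_length(p)
    straight <- vec_norm(p[nrow(p), ] - p[1L, ])
    vals <- c(vals, if (total == 0) 1 else straight / total)
  }
  if (!length(vals)) return(NULL)
  list(cell_id = cell_id, local_values = vals,
       mean_tortuosity = mean(vals))
}

#' Tortuosity table for a forest
#'
#' Applies [tortuosity()] to every cell and keeps the eligible ones.
#'
#' @inheritParams interval_speed
#' @param window_min,min_cycle_min,partial_min see [tortuosity()].
#' @return data.frame with `movie_id`, `cell_id`, `fate`,
#'   `mean_tortuosity`, `n_windows`.
#' @export
tortuosity_table <- function(forest, window_min = 50, min_cycle_min = 180,
                             partial_min = 25) {
  if (inherits(forest, "lineage_forest")) forest <- list(forest)
  rows <- list()
  for (f in forest) {
    fate <- derived_fates(f)
    for (cid in f$cells$cell_id) {
      r <- tortuosity(f, cid, window_min, min_cycle_min, partial_min)
      if (is.null(r)) next
      rows[[length(rows) + 1L]] <- data.frame(
        movie_id = f$movie_id, cell_id = cid, fate = unname(fate[cid]),
        mean_tortuosity = r$mean_tortuosity,
        n_windows = length(r$local_values), stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(movie_id = character(0), cell_id = character(0),
                  fate = character(0), mean_tortuosity = numeric(0),
                  n_windows = integer(0), stringsAsFactors = FALSE)
}

#' Contact distance threshold from confirmed-contact pairs
#'
#' The contact criterion is the arithmetic mean distance of visually
#' confirmed in-contact cell pairs (13 um in the source annotations of 57
#' pairs).
#'
#' @param samples numeric vector of confirmed-contact distances (um).
#' @return Mean distance in micrometres.
#' @export
derive_contact_threshold <- function(samples) {
  if (!length(samples)) stop_data("no contact distance samples")
  mean(samples)
}

#' Sister contact ratios after division
#'
#' For every sister pair in generations 1 and 2, measures the fraction of
#' their coexistence (within the first `window_min` aligned minutes,
#' default 16 h) spent closer than `threshold_um` (default 13 um).
#' Inter-sister distance is evaluated on the shared frame grid with linear
#' interpolation across small gaps. Pairs where either sister's cycle is
#' shorter than `min_cycle_min` are excluded. `contact_at_birth` flags
#' contact at the first coexistence frame (used for the retention rate).
#'
#' @param forest a `lineage_forest` or list of them.
#' @param threshold_um contact distance (default 13).
#' @param window_min aligned-time window (default 960 = 16 h).
#' @param min_cycle_min minimum sister cycle length (default 240 = 4 h).
#' @param generations daughter generations included (default 1:2).
#' @return data.frame with `movie_id`, `cell_a`, `cell_b`, `generation`,
#'   `contact_min`, `coexist_min`, `ratio`, `contact_at_birth`.
#' @export
contact_ratio <- function(forest, threshold_um = 13, window_min = 960,
                          min_cycle_min = 240, generations = 1:2) {
  if (inherits(forest, "lineage_forest")) forest <- list(forest)
  rows <- list()
  for (f in forest) {
    off <- f$meta$alignment_offset_min
    dt <- f$meta$frame_interval_min
    labs <- stats::setNames(f$cells$generation_label, f$cells$cell_id)
    life <- cell_life_table(f)
    dur <- stats::setNames(life$t_last - life$t_first, life$cell_id)
    for (cid in f$cells$cell_id) {
      kids <- forest_children(f, cid)
      if (length(kids) != 2L) next
      gen <- generation_of(labs[[kids[1L]]])
      if (!(gen %in% generations)) next
      if (any(dur[kids] < min_cycle_min)) next
      s1 <- cell_spots(f, kids[1L]); s2 <- cell_spots(f, kids[2L])
      t0 <- max(s1$t_min[1L], s2$t_min[1L])
      t1 <- min(s1$t_min[nrow(s1)], s2$t_min[nrow(s2)], window_min - off)
      if (t1 <= t0) next
      tt <- seq(t0, t1, by = dt)
      p1 <- interp_positions(s1$t_min, cell_pos_matrix(s1), tt)
      p2 <- interp_positions(s2$t_min, cell_pos_matrix(s2), tt)
      d <- row_norms(p1 - p2)
      ok <- !is.na(d)
      if (!any(ok)) next
      rows[[length(rows) + 1L]] <- data.frame(
        movie_id = f$movie_id, cell_a = kids[1L], cell_b = kids[2L],
        generation = gen,
        contact_min = sum(d[ok] < threshold_um) * dt,
        coexist_min = sum(ok) * dt,
        ratio = mean(d[ok] < threshold_um),
        contact_at_birth = d[which(ok)[1L]] < threshold_um,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(movie_id = character(0), cell_a = character(0),
                  cell_b = character(0), generation = integer(0),
                  contact_min = numeric(0), coexist_min = numeric(0),
                  ratio = numeric(0), contact_at_birth = logical(0),
                  stringsAsFactors = FALSE)
}

#' Post-division contact retention rate
#'
#' Fraction of sister pairs already in contact at their first coexistence
#' frame.
#'
#' @param records output of [contact_ratio()].
#' @return List with `rate` and `n`.
#' @export
contact_retention_rate <- function(records) {
  if (!nrow(records)) stop_data("no sister pairs")
  list(rate = mean(records$contact_at_birth), n = nrow(records))
}
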