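#' Anatomical axis specification
#'
#' An axis is a user-supplied segment in the imaging frame, established
#' empirically from anatomy (e.g. anterior-posterior or dorsal-ventral in
#' the heart tube).
#'
#' @param name axis name, typically `"AP"` or `"DV"`.
#' @param p0,p1 3-vectors in micrometres; must differ.
#' @return Object of class `axis_spec` with unit vector `u` and length `D`.
#' @export
axis_spec <- function(name, p0, p1) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  D <- vec_norm(p1 - p0)
  if (D <= 0) stop_data("axis endpoints must differ")
  structure(list(name = name, p0 = p0, p1 = p1, u = (p1 - p0) / D, D = D),
            class = "axis_spec")
}

# Position of cells at one time (movie clock), linearly interpolated within
# each life; cells not alive at t drop out.
positions_at <- function(forest, ids, t) {
  out <- matrix(NA_real_, length(ids), 3L,
                dimnames = list(ids, c("x_um", "y_um", "z_um")))
  for (i in seq_along(ids)) {
    s <- cell_spots(forest, ids[i])
    out[i, ] <- interp_positions(s$t_min, cell_pos_matrix(s), t)
  }
  out[stats::complete.cases(out), , drop = FALSE]
}

subtree_ids <- function(forest, root) {
  acc <- root; queue <- root
  while (length(queue)) {
    kids <- forest_children(forest, queue[1L]); queue <- queue[-1L]
    acc <- c(acc, kids); queue <- c(queue, kids)
  }
  acc
}

#' Clone spread along an anatomical axis
#'
#' Projects the clone's GFP-positive cells onto the axis and reports the
#' range of projections `d` as a fraction of the axis length `D`. Cells must
#' be alive at the sampling time, at least `min_cycle_age_min` into their
#' cell cycle (to discount short post-division displacements), and already
#' called GFP-positive. For the fraction, projections are clamped to
#' `[0, D]`; the unclamped range is reported as `d_raw`.
#'
#' @param forest a `lineage_forest`.
#' @param root clone (tree) root cell id.
#' @param axis an [axis_spec()].
#' @param threshold a `threshold_model` used to find GFP+ cells.
#' @param at_time sampling time on the movie clock (default: last tracked
#'   frame of the movie).
#' @param min_cycle_age_min minimum time into the cell cycle (default
#'   240 min).
#' @return data.frame row: `clone_id`, `axis`, `d`, `d_raw`, `D`,
#'   `fraction`, `n_cells`.
#' @export
clone_axis_spread <- function(forest, root, axis, threshold, at_time = NULL,
                              min_cycle_age_min = 240) {
  at_time <- at_time %||% max(forest$spots$t_min)
  ids <- subtree_ids(forest, root)
  life <- cell_life_table(forest)
  life <- life[life$cell_id %in% ids, , drop = FALSE]
  alive <- life$cell_id[life$t_first <= at_time & life$t_last >= at_time &
                          at_time - life$t_first >= min_cycle_age_min]
  calls <- call_differentiation(forest, threshold)
  gfp_pos <- calls$cell_id[!is.na(calls$t_diff_min) &
                             calls$t_diff_min <= at_time]
  elig <- intersect(alive, gfp_pos)
  pos <- positions_at(forest, elig, at_time)
  if (!nrow(pos))
    stop_data("empty-clone error: clone %s has no eligible GFP+ cell at t=%g",
              root, at_time)
  proj <- as.numeric((pos - matrix(axis$p0, nrow(pos), 3L, byrow = TRUE)) %*%
                       axis$u)
  clamped <- pmin(pmax(proj, 0), axis$D)
  data.frame(clone_id = root, axis = axis$name,
             d = diff(range(clamped)), d_raw = diff(range(proj)),
             D = axis$D, fraction = diff(range(clamped)) / axis$D,
             n_cells = nrow(pos), stringsAsFactors = FALSE)
}

#' Homotypic/heterotypic distance samples within one family
#'
#' Samples Euclidean distances between related cells at three family
#' timepoints: T0 (a fixed offset, default 20 min, after the mother's
#' division; daughters D1 vs D2), T1 (last time point before the daughters'
#' next division; D1 vs D2), and T2 (final time point at which all
#' granddaughters coexist, truncated at the end of migration; all
#' granddaughter pairs). Only branches at least `min_cycle_min` into their
#' cell cycle are considered, and each pair is tagged homotypic when both
#' determined fates agree, heterotypic when they differ; pairs with an
#' undetermined side are dropped.
#'
#' @param forest a `lineage_forest` with fates.
#' @param root family (tree) root cell id.
#' @param end_of_migration aligned minutes bounding T2 (default `Inf`).
#' @param t0_offset_min minutes after the first division for T0 (default
#'   20; 10 is the documented alternative).
#' @param min_cycle_min minimum branch duration (default 240).
#' @return data.frame with `family_id`, `cell_a`, `cell_b`, `timepoint`
#'   (T0/T1/T2), `kind`, `distance`, `t_min`.
#' @export
family_distance_samples <- function(forest, root, end_of_migration = Inf,
                                    t0_offset_min = 20, min_cycle_min = 240) {
  off <- forest$meta$alignment_offset_min
  fate <- derived_fates(forest)
  life <- cell_life_table(forest)
  dur <- stats::setNames(life$t_last - life$t_first, life$cell_id)
  rows <- list()
  pair_row <- function(a, b, tag, t) {
    fa <- fate[[a]]; fb <- fate[[b]]
    if (any(c(fa, fb) %in% c("UNDETERMINED", "MIXED"))) return(invisible(NULL))
    pos <- positions_at(forest, c(a, b), t)
    if (nrow(pos) < 2L) return(invisible(NULL))  # timepoint outside a span
    rows[[length(rows) + 1L]] <<- data.frame(
      family_id = root, cell_a = a, cell_b = b, timepoint = tag,
      kind = if (fa == fb) "homotypic" else "heterotypic",
      distance = vec_norm(pos[1L, ] - pos[2L, ]), t_min = t,
      stringsAsFactors = FALSE)
    invisible(NULL)
  }
  daughters <- forest_children(forest, root)
  if (length(daughters) == 2L &&
      all(dur[daughters] >= min_cycle_min)) {
    t_div <- life$t_last[life$cell_id == root]
    pair_row(daughters[1L], daughters[2L], "T0", t_div + t0_offset_min)
    t1 <- min(life$t_last[life$cell_id %in% daughters])
    pair_row(daughters[1L], daughters[2L], "T1", t1)
  }
  grand <- unlist(lapply(daughters, forest_children, forest = forest))
  grand <- grand[dur[grand] >= min_cycle_min]
  if (length(grand) >= 2L) {
    t2 <- min(c(life$t_last[life$cell_id %in% grand],
                end_of_migration - off))
    if (t2 >= max(life$t_first[life$cell_id %in% grand])) {
      cmb <- utils::combn(grand, 2L)
      for (k in seq_len(ncol(cmb)))
        pair_row(cmb[1L, k], cmb[2L, k], "T2", t2)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(family_id = character(0), cell_a = character(0),
                  cell_b = character(0), timepoint = character(0),
                  kind = character(0), distance = numeric(0),
                  t_min = numeric(0), stringsAsFactors = FALSE)
}

#' Distance between the midpoints of two sets of daughter positions
#'
#' Euclidean distance between the centroid of D1's daughters and the
#' centroid of D2's daughters.
#'
#' @param side1,side2 matrices of 3-D positions (one row per cell); each
#'   side needs at least one row.
#' @return Distance in micrometres.
#' @export
midpoint_distance <- function(side1, side2) {
  side1 <- rbind(side1); side2 <- rbind(side2)
  if (!nrow(side1) || !nrow(side2))
    stop_data("midpoint_distance: each side needs >= 1 position")
  vec_norm(colMeans(side1) - colMeans(side2))
}

#' Dispersion of sister myocytes at a developmental stage
#'
#' Pairwise distances among GFP-positive myocytes of the same family,
#' sampled either at the end of migration (the movie's mean LV/AVC
#' differentiation time) or at the last tracked frame (after heart tube
#' formation).
#'
#' @param forest a `lineage_forest` with fates.
#' @param threshold a `threshold_model`.
#' @param stage `"end_migration"` or `"heart_tube"`.
#' @param myocyte_fates fate classes counted as myocytes.
#' @return List with `distances` (data.frame family, pair, distance),
#'   `mean`, `sd`, `n`.
#' @export
sister_myocyte_dispersion <- function(forest, threshold,
                                      stage = c("end_migration", "heart_tube"),
                                      myocyte_fates = c("LV_AVC", "ATRIAL")) {
  stage <- match.arg(stage)
  t_sample <- if (stage == "end_migration")
    migration_end(forest, threshold) - forest$meta$alignment_offset_min
  else max(forest$spots$t_min)
  fate <- derived_fates(forest)
  calls <- call_differentiation(forest, threshold)
  gfp_pos <- calls$cell_id[!is.na(calls$t_diff_min) &
                             calls$t_diff_min <= t_sample]
  rows <- list()
  for (root in forest_roots(forest)) {
    ids <- subtree_ids(forest, root)
    ids <- ids[fate[ids] %in% myocyte_fates]
    ids <- intersect(ids, gfp_pos)
    pos <- positions_at(forest, ids, t_sample)
    if (nrow(pos) < 2L) next
    cmb <- utils::combn(rownames(pos), 2L)
    for (k in seq_len(ncol(cmb)))
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = root, cell_a = cmb[1L, k], cell_b = cmb[2L, k],
        distance = vec_norm(pos[cmb[1L, k], ] - pos[cmb[2L, k], ]),
        stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    warning("no eligible same-family GFP+ myocyte pair", call. = FALSE)
    return(list(distances = data.frame(), mean = NA_real_, sd = NA_real_,
                n = 0L))
  }
  d <- do.call(rbind, rows)
  list(distances = d, mean = mean(d$distance), sd = stats::sd(d$distance),
       n = nrow(d))
}

#' Classify a progenitor's potency from its descendants' fates
#'
#' Potency is the number of distinct determined fates among a tree's
#' leaves: uni-fated, bipotent, or tripotent (3+). If any leaf is
#' undetermined the mother is classed undetermined. The restriction
#' generation is the earliest generation at which every existing subtree is
#' fate-homogeneous (0 for a uni-fated mother).
#'
#' @param forest a `lineage_forest` with fates.
#' @param root tree root cell id.
#' @return List with `potency`, `n_fates`, `fates`, `restriction_generation`.
#' @export
classify_potency <- function(forest, root) {
  fate <- derived_fates(forest)
  leaves <- Filter(function(id) !length(forest_children(forest, id)),
                   subtree_ids(forest, root))
  leaf_fates <- unname(fate[leaves])
  det <- sort(setdiff(unique(leaf_fates), c("UNDETERMINED", "MIXED")))
  if (any(leaf_fates == "UNDETERMINED"))
    return(list(potency = "undetermined", n_fates = length(det), fates = det,
                restriction_generation = NA_integer_))
  potency <- c("uni-fated", "bipotent", "tripotent")[min(length(det), 3L)]
  homog_depth <- function(id, depth) {
    kids <- forest_children(forest, id)
    if (!length(kids) || fate[[id]] != "MIXED") return(depth)
    max(vapply(kids, homog_depth, 0L, depth = depth + 1L))
  }
  list(potency = potency, n_fates = length(det), fates = det,
       restriction_generation = homog_depth(root, 0L))
}
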