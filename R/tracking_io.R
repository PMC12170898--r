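#' Movie metadata
#'
#' Bundles the per-movie clock and calibration needed by every analysis:
#' the frame interval (2 min for the light-sheet acquisitions), background
#' intensity samples, the movie-wide maximum raw GFP (used for
#' normalisation), the temporal alignment offset, and optional anatomical
#' axis landmarks.
#'
#' @param movie_id character scalar identifying the movie.
#' @param frame_interval_min minutes between frames (> 0); default 2.
#' @param background_samples data.frame with columns `t_min`, `intensity`,
#'   or `NULL`.
#' @param gfp_max movie-wide maximum raw GFP over tracked spots, or `NULL`
#'   to fill in from data later.
#' @param alignment_offset_min minutes added to this movie's clock to place
#'   it on the common aligned timeline.
#' @param axis_landmarks optional named list of axes, each a list with 3-vectors
#'   `p0` and `p1` in micrometres (names typically `"AP"` and `"DV"`).
#' @return An object of class `movie_meta`.
#' @export
movie_meta <- function(movie_id, frame_interval_min = 2,
                       background_samples = NULL, gfp_max = NULL,
                       alignment_offset_min = 0, axis_landmarks = NULL) {
  if (frame_interval_min <= 0) stop_data("frame_interval_min must be > 0")
  if (!is.null(background_samples)) {
    background_samples <- as.data.frame(background_samples)
    if (!all(c("t_min", "intensity") %in% names(background_samples)))
      stop_data("background_samples needs columns t_min, intensity")
    background_samples <-
      background_samples[order(background_samples$t_min), , drop = FALSE]
  }
  if (!is.null(gfp_max) && gfp_max <= 0) stop_data("gfp_max must be > 0")
  structure(list(movie_id = as.character(movie_id),
                 frame_interval_min = frame_interval_min,
                 background_samples = background_samples,
                 gfp_max = gfp_max,
                 alignment_offset_min = alignment_offset_min,
                 axis_landmarks = axis_landmarks),
            class = "movie_meta")
}

#' @export
print.movie_meta <- function(x, ...) {
  cat("<movie_meta>", x$movie_id,
      sprintf("(%g min/frame, offset %+g min)\n",
              x$frame_interval_min, x$alignment_offset_min))
  invisible(x)
}

FATE_LEVELS <- c("LV_AVC", "ATRIAL", "ENDOCARDIUM", "PERICARDIUM", "EXEM",
                 "ENDOTHELIAL_LIKE", "MESO_GFP_NEG", "UNDETERMINED")

#' Fate classes recognised by the package
#'
#' The tracked mesodermal fates: LV/AVC and atrial myocytes, endocardium,
#' pericardium, extraembryonic mesoderm (ExEm), endothelial-like cells,
#' GFP-negative mesoderm, and UNDETERMINED for truncated tracks.
#'
#' @return Character vector of fate labels.
#' @export
fate_levels <- function() FATE_LEVELS

SPOT_COLS <- c("spot_id", "cell_id", "frame", "x_um", "y_um", "z_um",
               "gfp", "tdtomato")

new_forest <- function(cells, spots, meta) {
  rownames(cells) <- NULL
  rownames(spots) <- NULL
  structure(list(movie_id = meta$movie_id, cells = cells, spots = spots,
                 meta = meta),
            class = "lineage_forest")
}

#' @export
print.lineage_forest <- function(x, ...) {
  n <- count_forest(x)
  cat(sprintf("<lineage_forest> movie %s: %d mother cells, %d descendants, %d spots\n",
              x$movie_id, n[["n_mothers"]], n[["n_descendants"]],
              nrow(x$spots)))
  invisible(x)
}

#' Read a spot/link tracking table into a lineage forest
#'
#' Assembles cell lives and the division forest from the tabular export of
#' manual tracking. Spots carry one detection per cell per frame; link rows
#' connect a parent cell's last spot to each daughter's first spot (links
#' between spots of the same cell are tolerated and ignored). A cell life
#' with a gap longer than `max_gap_frames` missing frames is split into two
#' lives with a warning; shorter gaps are kept and interpolated by the
#' downstream metrics.
#'
#' @param spots_path CSV with columns `spot_id, cell_id, frame, x_um, y_um,
#'   z_um, gfp, tdtomato` (rename via `column_map`).
#' @param links_path CSV with columns `source_spot_id, target_spot_id`.
#' @param meta a [movie_meta()].
#' @param fates_path optional CSV with columns `cell_id, fate`.
#' @param column_map optional named character vector mapping the canonical
#'   column names to the names actually present in the files, e.g.
#'   `c(x_um = "POSITION_X")` — the adaptor for foreign tracking schemas.
#' @param max_gap_frames largest tolerated within-cell frame gap (default 5).
#' @return A `lineage_forest` with generation labels assigned.
#' @export
read_tracking_table <- function(spots_path, links_path, meta,
                                fates_path = NULL, column_map = NULL,
                                max_gap_frames = 5L) {
  spots <- utils::read.csv(spots_path, stringsAsFactors = FALSE)
  links <- utils::read.csv(links_path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      j <- match(column_map[[canon]], names(spots))
      if (!is.na(j)) names(spots)[j] <- canon
    }
  }
  missing_cols <- setdiff(SPOT_COLS, names(spots))
  if (length(missing_cols))
    stop_data("spot table format error: missing column(s) %s",
              paste(missing_cols, collapse = ", "))
  link_cols <- c("source_spot_id", "target_spot_id")
  if (!all(link_cols %in% names(links)))
    stop_data("link table format error: missing column(s) %s",
              paste(setdiff(link_cols, names(links)), collapse = ", "))
  fates <- NULL
  if (!is.null(fates_path)) {
    fates <- utils::read.csv(fates_path, stringsAsFactors = FALSE)
    if (!all(c("cell_id", "fate") %in% names(fates)))
      stop_data("fate table format error: needs columns cell_id, fate")
  }
  assemble_forest(spots, links, meta, fates, max_gap_frames)
}

#' Assemble a forest from in-memory tracking tables
#'
#' Same contract as [read_tracking_table()] but taking data.frames, which is
#' how the synthetic generator's output enters the pipeline.
#'
#' @param spots,links,fates data.frames with the canonical columns.
#' @param meta a [movie_meta()].
#' @param max_gap_frames largest tolerated within-cell frame gap.
#' @return A `lineage_forest`.
#' @export
assemble_forest <- function(spots, links, meta, fates = NULL,
                            max_gap_frames = 5L) {
  spots <- as.data.frame(spots)
  spots$spot_id <- as.character(spots$spot_id)
  spots$cell_id <- as.character(spots$cell_id)
  if (nrow(links)) {
    links <- data.frame(source_spot_id = as.character(links$source_spot_id),
                        target_spot_id = as.character(links$target_spot_id))
    known <- spots$spot_id
    bad <- c(setdiff(links$source_spot_id, known),
             setdiff(links$target_spot_id, known))
    if (length(bad))
      stop_data("link integrity error: unknown spot id(s) %s",
                paste(unique(bad), collapse = ", "))
  }
  spots <- spots[order(spots$cell_id, spots$frame), , drop = FALSE]
  spots$t_min <- spots$frame * meta$frame_interval_min

  # Split lives at gaps wider than max_gap_frames.
  split_ids <- character(0)
  for (cid in unique(spots$cell_id)) {
    idx <- which(spots$cell_id == cid)
    gaps <- diff(spots$frame[idx])
    cut <- which(gaps > max_gap_frames)
    if (length(cut)) {
      split_ids <- c(split_ids, cid)
      piece <- cumsum(c(0L, as.integer(seq_along(gaps) %in% cut)))
      new_ids <- ifelse(piece == 0L, cid, paste0(cid, ".s", piece + 1L))
      spots$cell_id[idx] <- new_ids
    }
  }
  if (length(split_ids))
    warning(sprintf("split %d cell live(s) at gaps > %d frames: %s",
                    length(split_ids), max_gap_frames,
                    paste(split_ids, collapse = ", ")), call. = FALSE)

  spot_cell <- spots$cell_id[match(seq_len(nrow(spots)), seq_len(nrow(spots)))]
  names(spot_cell) <- spots$spot_id
  cell_of <- function(sid) spot_cell[sid]
  parent_of <- character(0)
  if (nrow(links)) {
    src_cell <- cell_of(links$source_spot_id)
    tgt_cell <- cell_of(links$target_spot_id)
    div <- src_cell != tgt_cell
    parent_of <- src_cell[div]
    names(parent_of) <- tgt_cell[div]
    if (anyDuplicated(names(parent_of)))
      stop_data("link integrity error: cell(s) with multiple parents: %s",
                paste(unique(names(parent_of)[duplicated(names(parent_of))]),
                      collapse = ", "))
    n_children <- table(parent_of)
    bad <- names(n_children)[!(n_children %in% 2L)]
    if (length(bad))
      stop_data("lineage integrity error: cell(s) with child count not in {0,2}: %s",
                paste(bad, collapse = ", "))
  }
  cell_ids <- unique(spots$cell_id)
  cells <- data.frame(cell_id = cell_ids,
                      parent = unname(parent_of[cell_ids]),
                      generation_label = NA_character_,
                      fate = NA_character_,
                      stringsAsFactors = FALSE)
  if (!is.null(fates)) {
    m <- match(cells$cell_id, as.character(fates$cell_id))
    cells$fate <- as.character(fates$fate)[m]
  }
  spots <- spots[, c(SPOT_COLS, "t_min"), drop = FALSE]
  forest <- new_forest(cells, spots, meta)
  generation_labels(forest)
}

forest_roots <- function(forest) forest$cells$cell_id[is.na(forest$cells$parent)]

forest_children <- function(forest, cell_id) {
  forest$cells$cell_id[!is.na(forest$cells$parent) &
                         forest$cells$parent == cell_id]
}

#' Spots of one cell life, time-ordered
#'
#' @param forest a `lineage_forest`.
#' @param cell_id the cell life to extract.
#' @return data.frame of that cell's spots sorted by frame.
#' @export
cell_spots <- function(forest, cell_id) {
  s <- forest$spots[forest$spots$cell_id == cell_id, , drop = FALSE]
  s[order(s$frame), , drop = FALSE]
}

cell_pos_matrix <- function(spots_df) {
  as.matrix(spots_df[, c("x_um", "y_um", "z_um"), drop = FALSE])
}

# First/last tracked time of each cell in one pass.
cell_life_table <- function(forest) {
  sp <- forest$spots
  o <- order(sp$cell_id, sp$frame)
  sp <- sp[o, , drop = FALSE]
  first <- !duplicated(sp$cell_id)
  last <- !duplicated(sp$cell_id, fromLast = TRUE)
  data.frame(cell_id = sp$cell_id[first],
             t_first = sp$t_min[first], t_last = sp$t_min[last],
             frame_first = sp$frame[first], frame_last = sp$frame[last],
             stringsAsFactors = FALSE)
}

#' Validate lineage-forest invariants
#'
#' Checks the structural contracts: binary divisions (0 or 2 children),
#' strictly increasing frames within each cell life, `t_min` consistent with
#' the frame grid, finite positions, non-negative intensities, acyclic
#' parent structure, and generation labels consistent with tree position
#' where assigned. Reporting only: never throws.
#'
#' @param forest a `lineage_forest`.
#' @return data.frame with columns `rule`, `cell_id`, `detail`; zero rows
#'   iff the forest is valid.
#' @export
validate_forest <- function(forest) {
  bad <- list()
  note <- function(rule, cell_id, detail)
    bad[[length(bad) + 1L]] <<- data.frame(rule = rule, cell_id = cell_id,
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  cells <- forest$cells
  sp <- forest$spots
  kids <- table(cells$parent[!is.na(cells$parent)])
  for (p in names(kids)[!(kids %in% 2L)])
    note("binary_division", p, sprintf("%d children", kids[[p]]))
  for (p in setdiff(unique(cells$parent[!is.na(cells$parent)]), cells$cell_id))
    note("parent_exists", p, "parent cell id not present")
  sp_o <- sp[order(sp$cell_id, sp$frame), , drop = FALSE]
  same <- sp_o$cell_id[-1L] == sp_o$cell_id[-nrow(sp_o)]
  inv <- which(same & diff(sp_o$frame) <= 0)
  for (i in unique(sp_o$cell_id[inv]))
    note("monotone_frames", i, "non-increasing frame within cell life")
  off_grid <- abs(sp$t_min - sp$frame * forest$meta$frame_interval_min) > 1e-9
  for (i in unique(sp$cell_id[off_grid]))
    note("time_grid", i, "t_min != frame * frame_interval_min")
  nf <- !is.finite(sp$x_um) | !is.finite(sp$y_um) | !is.finite(sp$z_um)
  for (i in unique(sp$cell_id[nf])) note("finite_position", i, "non-finite position")
  neg <- (sp$gfp < 0) | (sp$tdtomato < 0)
  for (i in unique(sp$cell_id[neg & !is.na(neg)]))
    note("nonnegative_intensity", i, "negative intensity")
  # cycle check by walking up from every cell
  idx <- match(cells$parent, cells$cell_id)
  for (i in seq_len(nrow(cells))) {
    seen <- integer(0); j <- i
    while (!is.na(j)) {
      if (j %in% seen) { note("acyclic", cells$cell_id[i], "ancestry cycle"); break }
      seen <- c(seen, j); j <- idx[j]
    }
  }
  if (!all(is.na(cells$generation_label))) {
    for (i in seq_len(nrow(cells))) {
      lab <- cells$generation_label[i]
      if (is.na(lab)) next
      p <- idx[i]
      if (is.na(p)) {
        if (lab != "M") note("generation_label", cells$cell_id[i],
                             sprintf("root labelled %s, expected M", lab))
      } else {
        plab <- cells$generation_label[p]
        stem <- if (identical(plab, "M")) "D" else plab
        if (is.na(plab) ||
            !(lab %in% paste0(stem, 1:2)))
          note("generation_label", cells$cell_id[i],
               sprintf("label %s inconsistent with parent %s", lab, plab))
      }
    }
  }
  if (length(bad)) do.call(rbind, bad)
  else data.frame(rule = character(0), cell_id = character(0),
                  detail = character(0), stringsAsFactors = FALSE)
}

#' Assign generation labels (M, D1, D2, D11, ...)
#'
#' The root of each tree is the mother `M`; the two daughters of any cell
#' labelled `X` get `X1` and `X2` (with the mother's daughters written `D1`
#' and `D2`). The daughter with the smaller first spot id takes suffix 1, a
#' deterministic tie-break that makes labelling invariant to input row order.
#'
#' @param forest a `lineage_forest`.
#' @return The forest with `generation_label` filled in.
#' @export
generation_labels <- function(forest) {
  cells <- forest$cells
  lab <- stats::setNames(rep(NA_character_, nrow(cells)), cells$cell_id)
  first_spot <- stats::setNames(rep(NA_character_, nrow(cells)), cells$cell_id)
  sp <- forest$spots[order(forest$spots$cell_id, forest$spots$frame), ]
  fs <- sp[!duplicated(sp$cell_id), c("cell_id", "spot_id")]
  first_spot[fs$cell_id] <- fs$spot_id
  ord_key <- function(ids) {
    sid <- first_spot[ids]
    num <- suppressWarnings(as.numeric(sid))
    if (!anyNA(num)) order(num) else order(sid)
  }
  for (root in forest_roots(forest)) {
    lab[root] <- "M"
    queue <- root
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      kids <- forest_children(forest, cur)
      if (!length(kids)) next
      kids <- kids[ord_key(kids)]
      stem <- if (lab[cur] == "M") "D" else lab[cur]
      lab[kids] <- paste0(stem, seq_along(kids))
      queue <- c(queue, kids)
    }
  }
  forest$cells$generation_label <- unname(lab[forest$cells$cell_id])
  forest
}

# Generation number: M -> 0, D1/D2 -> 1, D11 -> 2, ...
generation_of <- function(label) {
  ifelse(label == "M", 0L, nchar(label) - 1L)
}

#' Count mothers and descendants
#'
#' @param forest a `lineage_forest` or list of them (movies pooled).
#' @return Named integer vector `c(n_mothers, n_descendants)`.
#' @export
count_forest <- function(forest) {
  if (inherits(forest, "lineage_forest")) forest <- list(forest)
  n_m <- 0L; n_d <- 0L
  for (f in forest) {
    n_m <- n_m + sum(is.na(f$cells$parent))
    n_d <- n_d + sum(!is.na(f$cells$parent))
  }
  c(n_mothers = n_m, n_descendants = n_d)
}

#' Export lineage trees as Newick strings
#'
#' One Newick string per tree, with node names the generation labels and
#' branch lengths the cell-cycle durations in minutes (last tracked time
#' minus first tracked time of each cell life). The mother carries no branch
#' length, so a lone mother exports as `"M;"`.
#'
#' @param forest a `lineage_forest` with generation labels.
#' @return Named character vector (names = root cell ids).
#' @export
export_newick <- function(forest) {
  life <- cell_life_table(forest)
  dur <- stats::setNames(life$t_last - life$t_first, life$cell_id)
  lab <- stats::setNames(forest$cells$generation_label, forest$cells$cell_id)
  rec <- function(id) {
    kids <- forest_children(forest, id)
    if (length(kids)) {
      kids <- kids[order(lab[kids])]
      inner <- paste(vapply(kids, function(k)
        paste0(rec(k), ":", format(dur[[k]], trim = TRUE)), ""),
        collapse = ",")
      paste0("(", inner, ")", lab[[id]])
    } else lab[[id]]
  }
  roots <- forest_roots(forest)
  stats::setNames(vapply(roots, function(r) paste0(rec(r), ";"), ""), roots)
}

#' Write a forest back to tracking tables
#'
#' Inverse of [read_tracking_table()]: writes the spot CSV, the link CSV
#' (consecutive-spot links within each life plus a division link from each
#' mother's last spot to each daughter's first spot), and optionally the
#' fate CSV.
#'
#' @param forest a `lineage_forest`.
#' @param spots_path,links_path,fates_path output CSV paths (`fates_path`
#'   optional).
#' @return Invisibly, the forest.
#' @export
write_tracking_table <- function(forest, spots_path, links_path,
                                 fates_path = NULL) {
  sp <- forest$spots[order(forest$spots$cell_id, forest$spots$frame), ]
  utils::write.csv(sp[, SPOT_COLS], spots_path, row.names = FALSE)
  links <- list()
  for (cid in forest$cells$cell_id) {
    ids <- sp$spot_id[sp$cell_id == cid]
    if (length(ids) > 1L)
      links[[length(links) + 1L]] <-
        data.frame(source_spot_id = ids[-length(ids)],
                   target_spot_id = ids[-1L])
  }
  for (i in which(!is.na(forest$cells$parent))) {
    cid <- forest$cells$cell_id[i]
    pid <- forest$cells$parent[i]
    p_last <- utils::tail(sp$spot_id[sp$cell_id == pid], 1L)
    c_first <- sp$spot_id[sp$cell_id == cid][1L]
    links[[length(links) + 1L]] <-
      data.frame(source_spot_id = p_last, target_spot_id = c_first)
  }
  links <- if (length(links)) do.call(rbind, links)
  else data.frame(source_spot_id = character(0), target_spot_id = character(0))
  utils::write.csv(links, links_path, row.names = FALSE)
  if (!is.null(fates_path)) {
    fa <- forest$cells[!is.na(forest$cells$fate), c("cell_id", "fate")]
    utils::write.csv(fa, fates_path, row.names = FALSE)
  }
  invisible(forest)
}

#' Determined fate of every cell life
#'
#' A leaf's fate is its annotation; an internal cell inherits a fate only if
#' all its determined descendant leaves agree, otherwise it is reported as
#' `"MIXED"`. Cells whose subtree contains an `UNDETERMINED` (or missing)
#' leaf and no disagreement among the rest keep the agreed fate; a subtree
#' with no determined leaf at all is `UNDETERMINED`.
#'
#' @param forest a `lineage_forest` with fate annotations on leaves.
#' @return Named character vector of fates keyed by cell id.
#' @export
derived_fates <- function(forest) {
  cells <- forest$cells
  out <- stats::setNames(rep(NA_character_, nrow(cells)), cells$cell_id)
  rec <- function(id) {
    kids <- forest_children(forest, id)
    if (!length(kids)) {
      f <- cells$fate[cells$cell_id == id]
      out[id] <<- if (is.na(f)) "UNDETERMINED" else f
      return(out[id])
    }
    sub <- vapply(kids, rec, "")
    det <- setdiff(unique(sub), c("UNDETERMINED", "MIXED"))
    out[id] <<- if ("MIXED" %in% sub || length(det) > 1L) "MIXED"
    else if (length(det) == 1L) det else "UNDETERMINED"
    out[id]
  }
  for (r in forest_roots(forest)) rec(r)
  out
}
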