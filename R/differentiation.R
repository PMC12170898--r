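#' Normalise GFP intensities within a movie
#'
#' Divides every spot's raw GFP by the movie-wide maximum (taken from
#' `meta$gfp_max` when set, otherwise from the tracked spots), so the
#' brightest tracked spot reads 1.
#'
#' @param forest a `lineage_forest`.
#' @return The forest with a `gfp_norm` spot column; `meta$gfp_max` filled.
#' @export
normalize_gfp <- function(forest) {
  gmax <- forest$meta$gfp_max %||% max(forest$spots$gfp)
  if (!is.finite(gmax) || gmax <= 0)
    stop_data("data error: movie gfp_max must be > 0")
  forest$meta$gfp_max <- gmax
  forest$spots$gfp_norm <- forest$spots$gfp / gmax
  forest
}

#' Piecewise-linear GFP background model
#'
#' Background intensity is sampled at intervals through the movie; between
#' samples the model interpolates linearly, beyond the sampled range it is
#' constant at the nearest sample.
#'
#' @param samples data.frame with columns `t_min`, `intensity` (>= 1 row).
#' @return Object of class `background_model`; evaluate with
#'   [background_value()].
#' @export
fit_background <- function(samples) {
  samples <- as.data.frame(samples)
  if (!nrow(samples)) stop_data("data error: no background samples")
  samples <- samples[order(samples$t_min), , drop = FALSE]
  fn <- if (nrow(samples) == 1L) {
    v <- samples$intensity[1L]
    function(t) rep(v, length(t))
  } else {
    stats::approxfun(samples$t_min, samples$intensity, rule = 2)
  }
  structure(list(samples = samples, fn = fn), class = "background_model")
}

#' Evaluate a background model
#'
#' @param model a `background_model`.
#' @param t times in minutes (movie clock).
#' @return Interpolated background intensities.
#' @export
background_value <- function(model, t) model$fn(t)

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("<background_model> %d samples over [%g, %g] min\n",
              nrow(x$samples), min(x$samples$t_min), max(x$samples$t_min)))
  invisible(x)
}

#' GFP-positivity threshold from endocardial traces
#'
#' The positivity threshold is `m` times the interpolated background, with
#' `m` the lowest multiplier that classifies every endocardial spot in the
#' movie as GFP-negative. Concretely
#' `m = (1 + eps) * max(gfp_raw / background(t))` over endocardial spots,
#' with `eps = 1e-6` making every endocardial spot strictly sub-threshold.
#'
#' @param forest a `lineage_forest` with fate annotations.
#' @param background a `background_model`.
#' @param endocardial_ids cell ids to use; default every cell whose
#'   determined fate is `ENDOCARDIUM`.
#' @param eps strictness margin (default 1e-6).
#' @return Object of class `threshold_model` with fields `multiplier`,
#'   `background`, `gfp_max`.
#' @export
find_threshold <- function(forest, background, endocardial_ids = NULL,
                           eps = 1e-6) {
  if (is.null(endocardial_ids)) {
    fate <- derived_fates(forest)
    endocardial_ids <- names(fate)[fate == "ENDOCARDIUM"]
  }
  if (!length(endocardial_ids))
    stop_data("data error: no endocardial cells to calibrate the threshold")
  sp <- forest$spots[forest$spots$cell_id %in% endocardial_ids, , drop = FALSE]
  bg <- background_value(background, sp$t_min)
  if (any(bg <= 0))
    stop_data("data error: background is <= 0 at an endocardial spot")
  m <- (1 + eps) * max(sp$gfp / bg)
  structure(list(multiplier = m, background = background,
                 gfp_max = forest$meta$gfp_max),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model> multiplier %.6g over interpolated background\n",
              x$multiplier))
  invisible(x)
}

# TRUE where a spot exceeds the threshold.
supra_threshold <- function(threshold, gfp_raw, t_min) {
  gfp_raw > threshold$multiplier * background_value(threshold$background, t_min)
}

#' Call differentiation times against the GFP threshold
#'
#' A cell differentiates at the first tracked time point whose raw GFP
#' exceeds `multiplier x background(t)`; with `persistence_frames = k` the
#' exceedance must hold for k consecutive tracked frames and the call is
#' the first frame of the run. Cells that never cross get `NA`.
#'
#' @param forest a `lineage_forest`.
#' @param threshold a `threshold_model`.
#' @param persistence_frames consecutive supra-threshold frames required
#'   (default 1).
#' @return data.frame with `cell_id`, `t_diff_min` (movie clock, `NA` if
#'   never called).
#' @export
call_differentiation <- function(forest, threshold, persistence_frames = 1L) {
  ids <- forest$cells$cell_id
  sup <- supra_threshold(threshold, forest$spots$gfp, forest$spots$t_min)
  out <- data.frame(cell_id = ids, t_diff_min = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    sel <- forest$spots$cell_id == ids[i]
    s <- sup[sel][order(forest$spots$frame[sel])]
    t <- sort(forest$spots$t_min[sel])
    k <- persistence_frames
    if (length(s) >= k) {
      runs <- if (k == 1L) s
      else vapply(seq_len(length(s) - k + 1L),
                  function(j) all(s[j:(j + k - 1L)]), TRUE)
      hit <- which(runs)[1L]
      if (!is.na(hit)) out$t_diff_min[i] <- t[hit]
    }
  }
  out
}

#' Mean differentiation time of a fate class
#'
#' @param forest a `lineage_forest`.
#' @param fate_class a fate label, e.g. `"LV_AVC"` or `"ATRIAL"`.
#' @param threshold a `threshold_model`.
#' @param persistence_frames passed to [call_differentiation()].
#' @return Mean called differentiation time (movie clock, minutes).
#' @export
mean_differentiation_time <- function(forest, fate_class, threshold,
                                      persistence_frames = 1L) {
  fate <- derived_fates(forest)
  ids <- names(fate)[fate == fate_class]
  calls <- call_differentiation(forest, threshold, persistence_frames)
  t <- calls$t_diff_min[calls$cell_id %in% ids]
  t <- t[!is.na(t)]
  if (!length(t))
    stop_data("empty-class error: no called %s cells", fate_class)
  mean(t)
}

#' Temporal alignment offsets from class mean differentiation times
#'
#' Aligns movies on the differentiation timing of the myocyte classes: the
#' offset of movie i is the average over shared fate classes of
#' (reference class mean - movie i class mean), rounded to the frame grid;
#' the reference movie's offset is 0. Downstream "aligned time" is
#' `t + offset`.
#'
#' @param class_means named list (one entry per movie) of named numeric
#'   vectors of class mean differentiation times in minutes, e.g.
#'   `list(m1 = c(LV_AVC = 1242, ATRIAL = 1745), ...)`.
#' @param reference name of the reference movie.
#' @param frame_interval_min frame grid for rounding (default 2).
#' @return Named numeric vector of offsets in minutes.
#' @export
align_movies <- function(class_means, reference, frame_interval_min = 2) {
  if (!reference %in% names(class_means))
    stop_data("alignment error: reference movie %s not present", reference)
  ref <- class_means[[reference]]
  out <- stats::setNames(numeric(length(class_means)), names(class_means))
  for (m in names(class_means)) {
    if (m == reference) next
    shared <- intersect(names(ref), names(class_means[[m]]))
    if (!length(shared))
      stop_data("alignment error: movie %s shares no fate class with the reference",
                m)
    d <- mean(ref[shared] - class_means[[m]][shared])
    out[m] <- round(d / frame_interval_min) * frame_interval_min
  }
  out
}

#' End of the migration period for a movie
#'
#' Migration ends at the mean differentiation time of the relevant myocyte
#' class: LV/AVC for the cardiac-crescent lineages, atrial for the atrial
#' analyses. Returned on the aligned clock (class mean + movie offset).
#'
#' @param forest a `lineage_forest`.
#' @param threshold a `threshold_model`.
#' @param fate_class `"LV_AVC"` (default) or `"ATRIAL"`.
#' @param persistence_frames passed through.
#' @return Aligned time in minutes.
#' @export
migration_end <- function(forest, threshold, fate_class = "LV_AVC",
                          persistence_frames = 1L) {
  mean_differentiation_time(forest, fate_class, threshold,
                            persistence_frames) +
    forest$meta$alignment_offset_min
}
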