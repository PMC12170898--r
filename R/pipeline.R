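#' Run the full lineage-motility pipeline
#'
#' Orchestrates every stage on one or more movies: GFP normalisation,
#' background fitting, threshold calibration on endocardial cells,
#' differentiation calling, temporal alignment on myocyte class means,
#' migration-end determination, speed / tortuosity / contact metrics,
#' sister-pair DTW, the uni-vs-bipotent permutation test, and the log-DTW
#' classification counts. Deterministic given `config$seed`.
#'
#' @param config either a YAML file path or a list with elements:
#'   \describe{
#'     \item{movies}{list of per-movie entries, each with `spots`, `links`,
#'       optionally `fates` (data.frames or CSV paths) and a `meta`
#'       ([movie_meta()]) or `movie_id` + `background` samples;}
#'     \item{synthetic}{alternatively, arguments for [sim_config()] (plus
#'       `seed`) to simulate the input instead;}
#'     \item{reference_movie}{movie id used as alignment reference
#'       (default: first movie);}
#'     \item{parameters}{optional list: `t0_offset_min` (20),
#'       `contact_threshold_um` (13), `contact_window_min` (960),
#'       `n_perm` (10000), `logdtw_threshold` (4.5), `bin_hours` (5),
#'       `persistence_frames` (1), `dtw_cadence` (1), `seed` (1).}
#'   }
#' @param outdir optional directory; when given, one tidy CSV per analysis
#'   and a `summary.json` are written there.
#' @return Object of class `pipeline_results`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  par <- config$parameters %||% list()
  p <- list(t0_offset_min = par$t0_offset_min %||% 20,
            contact_threshold_um = par$contact_threshold_um %||% 13,
            contact_window_min = par$contact_window_min %||% 960,
            n_perm = par$n_perm %||% 10000L,
            logdtw_threshold = par$logdtw_threshold %||% 4.5,
            bin_hours = par$bin_hours %||% 5,
            persistence_frames = par$persistence_frames %||% 1L,
            dtw_cadence = par$dtw_cadence %||% 1L,
            seed = par$seed %||% 1L)
  set.seed(p$seed)
  forests <- load_pipeline_movies(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_data("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  forests <- stage("normalize_gfp", lapply(forests, normalize_gfp))
  thresholds <- stage("threshold", lapply(forests, function(f)
    find_threshold(f, fit_background(f$meta$background_samples))))
  names(thresholds) <- vapply(forests, `[[`, "", "movie_id")
  class_means <- stage("differentiation", lapply(seq_along(forests), function(i) {
    f <- forests[[i]]
    out <- c()
    for (cl in c("LV_AVC", "ATRIAL")) {
      v <- tryCatch(mean_differentiation_time(f, cl, thresholds[[i]],
                                              p$persistence_frames),
                    error = function(e) NA_real_)
      if (!is.na(v)) out[cl] <- v
    }
    out
  }))
  names(class_means) <- names(thresholds)
  reference <- config$reference_movie %||% names(class_means)[1L]
  offsets <- stage("alignment",
                   align_movies(class_means, reference,
                                forests[[1L]]$meta$frame_interval_min))
  for (i in seq_along(forests))
    forests[[i]]$meta$alignment_offset_min <- offsets[[forests[[i]]$movie_id]]
  mig_end <- stage("migration_end", vapply(seq_along(forests), function(i)
    tryCatch(migration_end(forests[[i]], thresholds[[i]]),
             error = function(e) NA_real_), 0))
  names(mig_end) <- names(thresholds)
  end_mig_pooled <- mean(mig_end, na.rm = TRUE)
  speeds <- stage("speed", interval_speed(forests, bin_hours = p$bin_hours))
  tort <- stage("tortuosity", tortuosity_table(forests))
  contacts <- stage("contact",
                    contact_ratio(forests,
                                  threshold_um = p$contact_threshold_um,
                                  window_min = p$contact_window_min))
  retention <- if (nrow(contacts)) contact_retention_rate(contacts)
  else list(rate = NA_real_, n = 0L)
  fam <- stage("family_distances", do.call(rbind, unlist(lapply(
    forests, function(f) lapply(forest_roots(f), function(r)
      family_distance_samples(f, r, end_of_migration = end_mig_pooled,
                              t0_offset_min = p$t0_offset_min))),
    recursive = FALSE)))
  pairs <- stage("dtw", pair_dtw_table(forests,
                                       end_of_migration = end_mig_pooled,
                                       cadence = p$dtw_cadence))
  uni <- pairs$log_dtw[pairs$category %in% c("Uni", "UniExEm") &
                         !is.na(pairs$log_dtw) & !is.na(pairs$category)]
  bi <- pairs$log_dtw[pairs$category %in% c("Bi", "BiExEm") &
                        !is.na(pairs$log_dtw) & !is.na(pairs$category)]
  perm <- if (length(uni) && length(bi))
    stage("permutation",
          permutation_test(uni, bi, n_perm = p$n_perm, seed = p$seed,
                           exact = FALSE))
  logdtw_counts <- stage("logdtw", classify_by_logdtw(pairs,
                                                      p$logdtw_threshold))
  counts <- count_forest(forests)
  summary <- list(
    n_movies = length(forests),
    n_mothers = unname(counts[["n_mothers"]]),
    n_descendants = unname(counts[["n_descendants"]]),
    thresholds = lapply(thresholds, `[[`, "multiplier"),
    offsets_min = as.list(offsets),
    migration_end_min = as.list(mig_end),
    contact_retention = retention,
    n_dtw_pairs = nrow(pairs),
    permutation_p = if (!is.null(perm)) perm$p_value else NA,
    observed_logdtw_diff = if (!is.null(perm)) perm$observed_diff else NA,
    logdtw_counts = logdtw_counts,
    parameters = p)
  res <- structure(list(forests = forests, thresholds = thresholds,
                        class_means = class_means, offsets = offsets,
                        migration_end = mig_end, speeds = speeds,
                        tortuosity = tort, contacts = contacts,
                        family_distances = fam, pairs = pairs, perm = perm,
                        summary = summary),
                   class = "pipeline_results")
  if (!is.null(outdir)) write_pipeline_outputs(res, outdir)
  res
}

load_pipeline_movies <- function(config) {
  if (!is.null(config$synthetic)) {
    args <- config$synthetic
    seed <- args$seed %||% 1L
    args$seed <- NULL
    sim <- generate_embryo(do.call(sim_config, args), seed = seed)
    return(as_forests(sim))
  }
  if (is.null(config$movies)) stop_data("config error: no movies or synthetic block")
  lapply(config$movies, function(m) {
    meta <- m$meta
    if (is.null(meta)) {
      bg <- m$background
      if (is.character(bg)) bg <- utils::read.csv(bg)
      meta <- movie_meta(m$movie_id, m$frame_interval_min %||% 2,
                         background_samples = bg)
    }
    if (is.character(m$spots))
      read_tracking_table(m$spots, m$links, meta, fates_path = m$fates,
                          column_map = m$column_map)
    else
      assemble_forest(m$spots, m$links, meta, fates = m$fates)
  })
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.csv(df, file.path(outdir, paste0(name, ".csv")),
                     row.names = FALSE)
  w(res$speeds, "speeds")
  w(res$tortuosity, "tortuosity")
  w(res$contacts, "contacts")
  if (!is.null(res$family_distances)) w(res$family_distances, "family_distances")
  w(res$pairs, "dtw_pairs")
  jsonlite::write_json(res$summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' @export
print.pipeline_results <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<pipeline_results> %d movie(s): %d mothers, %d descendants\n",
              s$n_movies, s$n_mothers, s$n_descendants))
  cat(sprintf("  DTW pairs: %d; permutation p (uni < bi): %s\n",
              s$n_dtw_pairs, format(s$permutation_p, digits = 3)))
  invisible(x)
}

#' Diagnostic figures for a results bundle
#'
#' Writes standard report panels as PNG files: per-fate speed boxplots per
#' 5-h bin, log-DTW boxplots per pair category, tortuosity per fate, the
#' mean per-step DTW curve with a standard-error band, and a lineage tree
#' per movie coloured by normalised GFP. Boxes span the quartiles with the
#' median line, whiskers extend to the data minimum and maximum. Empty
#' groups are annotated and omitted.
#'
#' @param res a `pipeline_results`.
#' @param outdir output directory for the figures.
#' @return Invisibly, the vector of files written.
#' @export
plot_reports <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  panel <- function(name, fn) {
    path <- file.path(outdir, paste0(name, ".png"))
    grDevices::png(path, width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    fn()
    files <<- c(files, path)
  }
  minmax_box <- function(values, groups, main, ylab) {
    keep <- !is.na(values) & !is.na(groups)
    values <- values[keep]; groups <- droplevels(factor(groups[keep]))
    if (!length(values)) {
      graphics::plot.new(); graphics::title(main)
      graphics::text(0.5, 0.5, "no data"); return(invisible())
    }
    graphics::boxplot(values ~ groups, range = 0, main = main, ylab = ylab,
                      xlab = "", las = 2, col = "grey85")
  }
  if (nrow(res$speeds))
    panel("speed_by_fate", function()
      minmax_box(res$speeds$speed_um_min,
                 paste(res$speeds$fate, res$speeds$bin, sep = "."),
                 "Speed by fate and 5-h interval", "um/min"))
  if (nrow(res$tortuosity))
    panel("tortuosity_by_fate", function()
      minmax_box(res$tortuosity$mean_tortuosity, res$tortuosity$fate,
                 "Mean tortuosity by fate", "tortuosity"))
  if (nrow(res$pairs))
    panel("logdtw_by_category", function()
      minmax_box(res$pairs$log_dtw, res$pairs$category,
                 "log DTW by pair category", "log DTW"))
  pt <- pair_dtw_table(res$forests, keep_alignments = TRUE)
  al <- attr(pt, "alignments")
  if (length(al)) {
    crv <- mean_dtw_curve(al)
    panel("dtw_curve", function() {
      ok <- !is.na(crv$mean)
      graphics::plot(crv$step[ok], crv$mean[ok], type = "l", lwd = 2,
                     xlab = "warping-path step", ylab = "mean cumulative DTW",
                     main = "Mean DTW over the first 40 steps")
      graphics::polygon(c(crv$step[ok], rev(crv$step[ok])),
                        c(crv$mean[ok] - crv$se[ok],
                          rev(crv$mean[ok] + crv$se[ok])),
                        col = grDevices::adjustcolor("steelblue", 0.3),
                        border = NA)
    })
  }
  for (f in res$forests) {
    nwk <- export_newick(f)
    nwk <- nwk[vapply(nwk, function(s) grepl("(", s, fixed = TRUE), TRUE)]
    if (!length(nwk)) next
    tr <- ape::read.tree(text = nwk[[1L]])
    panel(paste0("lineage_tree_", f$movie_id), function()
      ape::plot.phylo(tr, main = paste("Lineage tree,", f$movie_id,
                                       "(first dividing clone)")))
    break
  }
  invisible(files)
}
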