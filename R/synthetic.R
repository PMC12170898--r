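#' Default fate-by-interval speed profile
#'
#' Mean speeds (um/min) per fate class in consecutive 5-hour bins of the
#' aligned (embryo) clock, encoding the observed phenomenology: ExEm cells
#' start slowest and accelerate through heart-tube formation; endocardial
#' and endothelial-like cells step up sharply in the 10-15 h interval;
#' pericardial cells slow down over the same window; myocytes drift slower
#' as they epithelialise.
#'
#' @return 7 x 9 numeric matrix, rows = fates, columns = 5-h bins.
#' @export
default_speed_profile <- function() {
  m <- rbind(
    LV_AVC           = c(.58, .55, .47, .42, .38, .34, .33, .32, .32),
    ATRIAL           = c(.50, .48, .44, .40, .37, .35, .34, .33, .33),
    ENDOCARDIUM      = c(.38, .44, .80, .68, .60, .55, .50, .48, .48),
    PERICARDIUM      = c(.54, .52, .34, .30, .28, .26, .25, .25, .25),
    EXEM             = c(.30, .50, .60, .70, .75, .80, .82, .84, .84),
    ENDOTHELIAL_LIKE = c(.40, .46, .74, .62, .56, .52, .49, .46, .46),
    MESO_GFP_NEG     = c(.46, .45, .42, .38, .36, .33, .31, .30, .30))
  colnames(m) <- paste0("h", seq(0, 40, by = 5))
  m
}

#' Configuration for the synthetic embryo generator
#'
#' Defaults emulate the tracked light-sheet study: 5 movies at 2-min
#' frames, movie starts staggered on the embryo clock by the published
#' alignment offsets (reference movie 2), about 45 mother cells per movie
#' over 7 fate classes, lineages up to 5 generations with lognormal cycle
#' lengths, fate-specific speed regimes ([default_speed_profile()]),
#' persistent-random-walk trajectories whose sister coupling depends on
#' shared vs distinct fate, logistic GFP onset for myocytes, and an
#' endocardial intensity ceiling at `endo_margin` times the drifting
#' background.
#'
#' @param n_movies,frames_per_movie,frame_interval_min movie grid.
#' @param movie_start_min embryo-clock time at each movie's local frame 0.
#' @param reference_movie index of the alignment reference.
#' @param n_mothers_per_fate named counts of mother cells per movie.
#' @param p_bipotent probability a mother is bipotent (two subtree fates).
#' @param birth_time_windows named list of `(min, max)` embryo-clock birth
#'   windows in minutes.
#' @param cycle_length `c(mean_min, sd_min)` of the lognormal cell cycle.
#' @param max_generations deepest generation simulated (mother = 0).
#' @param speed_profile fate x 5-h-bin speed matrix (um/min).
#' @param bin_hours width of the speed-profile bins.
#' @param persistence named per-fate directional autocorrelation in [0, 1).
#' @param sister_corr_uni,sister_corr_bi shared-heading weight in [0, 1]
#'   for same-fate and distinct-fate sister pairs.
#' @param gfp_onset named list of `c(mean_min, sd_min)` embryo-clock onset
#'   distributions for the differentiating (myocyte) fates.
#' @param gfp_rise_min duration of the logistic GFP rise (2%-98%).
#' @param gfp_amplitude plateau GFP as a multiple of background level.
#' @param gfp_background `c(level, drift_per_min, noise_sd)`; `noise_sd`
#'   is measurement noise on the background samples.
#' @param background_sample_interval_min background sampling cadence.
#' @param endo_margin hard ceiling of endocardial intensity as a multiple
#'   of the true background (the ground truth recovered by
#'   [find_threshold()]).
#' @param separation_bias named per-fate (plus `"BIPOTENT"`) weight of the
#'   outward heading bias that drives post-division sister separation.
#' @param initial_separation_um `(min, max)` uniform inter-sister distance
#'   at birth.
#' @param speed_noise_sdlog lognormal sd of multiplicative step-length
#'   noise (mean 1).
#' @param undetermined_frac fraction of leaves whose annotation is masked
#'   to UNDETERMINED.
#' @param seed default RNG seed for [generate_embryo()].
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_movies = 5L,
                       frames_per_movie = 1260L,
                       frame_interval_min = 2,
                       movie_start_min = c(74, 0, 239, 373, 626),
                       reference_movie = 2L,
                       n_mothers_per_fate = c(LV_AVC = 12L, ATRIAL = 6L,
                                              ENDOCARDIUM = 8L,
                                              PERICARDIUM = 8L, EXEM = 6L,
                                              ENDOTHELIAL_LIKE = 3L,
                                              MESO_GFP_NEG = 2L),
                       p_bipotent = 0.2,
                       birth_time_windows = list(
                         LV_AVC = c(0, 400), PERICARDIUM = c(0, 400),
                         ENDOCARDIUM = c(0, 500), EXEM = c(0, 400),
                         ENDOTHELIAL_LIKE = c(200, 600),
                         ATRIAL = c(400, 900), MESO_GFP_NEG = c(0, 600)),
                       cycle_length = c(mean_min = 600, sd_min = 150),
                       max_generations = 5L,
                       speed_profile = default_speed_profile(),
                       bin_hours = 5,
                       persistence = c(LV_AVC = 0.7, ATRIAL = 0.7,
                                       ENDOCARDIUM = 0.6, PERICARDIUM = 0.7,
                                       EXEM = 0.4, ENDOTHELIAL_LIKE = 0.6,
                                       MESO_GFP_NEG = 0.6),
                       sister_corr_uni = 0.9,
                       sister_corr_bi = 0.1,
                       gfp_onset = list(LV_AVC = c(mean_min = 1300, sd_min = 90),
                                        ATRIAL = c(mean_min = 1815, sd_min = 90)),
                       gfp_rise_min = 60,
                       gfp_amplitude = 6,
                       gfp_background = c(level = 100, drift_per_min = 0.05,
                                          noise_sd = 0),
                       background_sample_interval_min = 60,
                       endo_margin = 1.5,
                       separation_bias = c(LV_AVC = 0.05, ATRIAL = 0.05,
                                           ENDOCARDIUM = 0.1,
                                           PERICARDIUM = 0.02, EXEM = 0.15,
                                           ENDOTHELIAL_LIKE = 0.1,
                                           MESO_GFP_NEG = 0.1,
                                           BIPOTENT = 0.5),
                       initial_separation_um = c(3, 19),
                       speed_noise_sdlog = 0.3,
                       undetermined_frac = 0.1,
                       seed = 1L) {
  cfg <- as.list(environment())
  n_movies <- as.integer(n_movies)
  if (length(cfg$movie_start_min) == 1L)
    cfg$movie_start_min <- rep(cfg$movie_start_min, n_movies)
  if (length(cfg$movie_start_min) != n_movies)
    stop_data("config error: movie_start_min needs one value per movie")
  stopifnot(cfg$frame_interval_min > 0, cfg$frames_per_movie >= 10)
  for (w in c(cfg$sister_corr_uni, cfg$sister_corr_bi, cfg$p_bipotent,
              cfg$undetermined_frac))
    if (w < 0 || w > 1) stop_data("config error: weight %g outside [0, 1]", w)
  if (any(cfg$persistence < 0 | cfg$persistence >= 1))
    stop_data("config error: persistence must lie in [0, 1)")
  dur <- cfg$frames_per_movie * cfg$frame_interval_min
  for (f in names(cfg$n_mothers_per_fate)) {
    if (cfg$n_mothers_per_fate[[f]] == 0L) next
    win <- cfg$birth_time_windows[[f]]
    if (is.null(win)) stop_data("config error: no birth window for %s", f)
    if (any(win[1L] >= cfg$movie_start_min + dur))
      stop_data("config error: %s birth window starts beyond a movie's end", f)
  }
  if (!all(names(cfg$n_mothers_per_fate) %in% rownames(cfg$speed_profile)))
    stop_data("config error: speed profile misses a fate class")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d movie(s) x %d frames @ %g min, %d mothers/movie, seed %d\n",
              x$n_movies, x$frames_per_movie, x$frame_interval_min,
              sum(x$n_mothers_per_fate), x$seed))
  invisible(x)
}

lnorm_pars <- function(mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic tracked embryo
#'
#' Simulates the configured movies and returns, for each, the spot, link
#' and fate tables in the canonical tracking schema plus a [movie_meta()]
#' and a per-cell ground-truth table (`fate_true`, GFP onset, the sister
#' coupling weight in force at the cell's birth, and the mother's potency).
#' Identical `config` and `seed` give identical output.
#'
#' Trajectories are persistent random walks with per-fate heading
#' autocorrelation; each sister's step heading mixes a shared pair heading
#' (weight `sister_corr_uni` or `sister_corr_bi`) with its own, plus a
#' small outward bias that separates the pair over time. Step length is the
#' profile speed times multiplicative lognormal noise with mean one, so
#' realised mean speeds match the profile. Myocyte GFP rises logistically
#' at fate-specific onsets over a drifting linear background; endocardial
#' (and other reporter-negative) traces stay strictly below
#' `endo_margin` times the true background.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (default `config$seed`).
#' @return Object of class `synthetic_embryo`: list with `movies` (each
#'   holding `spots`, `links`, `fates`, `meta`, `truth`), `config`, `seed`.
#' @export
generate_embryo <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  cl <- lnorm_pars(config$cycle_length[["mean_min"]],
                   config$cycle_length[["sd_min"]])
  dt <- config$frame_interval_min
  total_f <- config$frames_per_movie
  bw <- config$bin_hours * 60
  bg_level <- config$gfp_background[["level"]]
  bg_drift <- config$gfp_background[["drift_per_min"]]
  rise_scale <- config$gfp_rise_min / 8
  sn <- config$speed_noise_sdlog
  movies <- vector("list", config$n_movies)
  for (mv in seq_len(config$n_movies)) {
    movie_id <- sprintf("sim%02d", mv)
    start_m <- config$movie_start_min[mv]
    bg_true <- function(t_local) bg_level + bg_drift * t_local
    speed_at <- function(fate, t_local) {
      b <- min(floor((t_local + start_m) / bw) + 1L, ncol(config$speed_profile))
      config$speed_profile[fate, max(b, 1L)]
    }
    cells <- list()   # each: id, parent, fate, frames, pos, w_pair, onset
    add_cell <- function(rec) cells[[length(cells) + 1L]] <<- rec
    onset_cache <- new.env(parent = emptyenv())

    family_onset <- function(tree_tag, fate) {
      key <- paste(tree_tag, fate)
      if (!is.null(onset_cache[[key]])) return(onset_cache[[key]])
      par <- config$gfp_onset[[fate]]
      v <- if (is.null(par)) NA_real_
      else stats::rnorm(1L, par[["mean_min"]], par[["sd_min"]]) - start_m
      onset_cache[[key]] <- v
      v
    }

    # simulate one cell's positions over frames f0..f1 (f0 row = start_pos)
    sim_walk <- function(f0, f1, fate, start_pos, h0, w, H_sh, bias) {
      nf <- f1 - f0 + 1L
      pos <- matrix(NA_real_, nf, 3L)
      pos[1L, ] <- start_pos
      h <- h0
      rho <- config$persistence[[fate]]
      if (nf > 1L) {
        xi <- random_units(nf - 1L)
        noise <- stats::rlnorm(nf - 1L, -sn^2 / 2, sn)
        for (k in seq_len(nf - 1L)) {
          h <- unit(rho * h + (1 - rho) * xi[k, ])
          dir <- if (w > 0) unit(w * H_sh[k, ] + (1 - w) * h + bias)
          else unit(h + bias)
          s <- speed_at(fate, (f0 + k - 1L) * dt)
          pos[k + 1L, ] <- pos[k, ] + dir * s * dt * noise[k]
        }
      }
      list(pos = pos, h = h)
    }

    # recursive simulation of a subtree pair structure
    sim_subtree <- function(tree_tag, label, fate, birth_f, gen, start_pos,
                            h0, w, H_sh, bias, potency) {
      cyc_f <- max(3L, round(stats::rlnorm(1L, cl[["meanlog"]],
                                           cl[["sdlog"]]) / dt))
      death_f <- birth_f + cyc_f
      onset_self <- family_onset(tree_tag, fate)
      # differentiated myocytes exit the cycle: no divisions past the
      # family's reporter onset
      divides <- gen < config$max_generations && death_f <= total_f - 3L &&
        (is.na(onset_self) || death_f * dt <= onset_self)
      if (!divides) death_f <- min(death_f, total_f)
      wk <- sim_walk(birth_f, death_f, fate, start_pos, h0, w, H_sh, bias)
      add_cell(list(id = paste0(movie_id, "_", tree_tag, "_", label),
                    tree = tree_tag, label = label, fate = fate,
                    parent = NULL, birth_f = birth_f, death_f = death_f,
                    pos = wk$pos, w_pair = w, leaf = !divides,
                    potency = potency,
                    onset = family_onset(tree_tag, fate)))
      idx_self <- length(cells)
      if (divides) {
        b_f <- death_f + 1L
        # daughter subtree fates: bipotent mothers split at generation 1
        fates_d <- if (gen == 0L && potency == "bipotent") {
          others <- setdiff(names(config$n_mothers_per_fate), fate)
          c(fate, sample(others, 1L))
        } else c(fate, fate)
        w_d <- if (fates_d[1L] == fates_d[2L]) config$sister_corr_uni
        else config$sister_corr_bi
        bias_key <- if (fates_d[1L] == fates_d[2L]) fates_d[1L] else "BIPOTENT"
        bias_w <- config$separation_bias[[bias_key]] %||% 0
        sep <- stats::runif(1L, config$initial_separation_um[1L],
                            config$initial_separation_um[2L])
        u_sep <- random_units(1L)[1L, ]
        p_end <- wk$pos[nrow(wk$pos), ]
        # shared pair heading: persistent walk continuing the mother's
        span <- total_f - b_f + 2L
        rho_p <- config$persistence[[fate]]
        H <- matrix(NA_real_, span, 3L)
        hh <- wk$h
        xi <- random_units(span)
        for (k in seq_len(span)) {
          hh <- unit(rho_p * hh + (1 - rho_p) * xi[k, ])
          H[k, ] <- hh
        }
        lab_d <- if (label == "M") c("D1", "D2")
        else paste0(label, 1:2)
        for (j in 1:2) {
          idx_child <- sim_subtree(tree_tag, lab_d[j], fates_d[j], b_f,
                                   gen + 1L,
                                   p_end + (if (j == 1L) 0.5 else -0.5) * sep * u_sep,
                                   wk$h, w_d, H,
                                   (if (j == 1L) 1 else -1) * bias_w * u_sep,
                                   potency = potency)
          cells[[idx_child]]$parent <<- cells[[idx_self]]$id
        }
      }
      idx_self
    }

    tree_i <- 0L
    for (fate in names(config$n_mothers_per_fate)) {
      for (k in seq_len(config$n_mothers_per_fate[[fate]])) {
        tree_i <- tree_i + 1L
        win <- config$birth_time_windows[[fate]]
        birth_local <- stats::runif(1L, win[1L], win[2L]) - start_m
        birth_f <- max(0L, ceiling(birth_local / dt))
        if (birth_f >= total_f - 3L) next  # never visible in this movie
        potency <- if (stats::runif(1L) < config$p_bipotent) "bipotent"
        else "uni-fated"
        start_pos <- c(stats::runif(2L, 0, 400), stats::runif(1L, 0, 200))
        sim_subtree(sprintf("t%03d", tree_i), "M", fate, birth_f, 0L,
                    start_pos, random_units(1L)[1L, ], 0,
                    matrix(0, 1L, 3L), c(0, 0, 0), potency)
      }
    }

    # ---- intensity traces and tables -------------------------------------
    spot_rows <- vector("list", length(cells))
    next_spot <- 0L
    for (ci in seq_along(cells)) {
      ce <- cells[[ci]]
      ff <- ce$birth_f:ce$death_f
      t_loc <- ff * dt
      bg <- bg_true(t_loc)
      n <- length(ff)
      gfp <- if (ce$fate %in% names(config$gfp_onset)) {
        bg * config$endo_margin * stats::runif(n, 0.3, 0.9) +
          config$gfp_amplitude * bg_level *
          stats::plogis((t_loc - ce$onset) / rise_scale)
      } else if (ce$fate == "ENDOCARDIUM") {
        bg * config$endo_margin * stats::runif(n, 0.3, 1)
      } else {
        bg * config$endo_margin * stats::runif(n, 0.2, 0.9)
      }
      spot_rows[[ci]] <- data.frame(
        spot_id = as.character(next_spot + seq_len(n)),
        cell_id = ce$id, frame = ff,
        x_um = ce$pos[, 1L], y_um = ce$pos[, 2L], z_um = ce$pos[, 3L],
        gfp = gfp, tdtomato = stats::runif(1L, 300, 800) *
          stats::rlnorm(n, -0.005, 0.1), stringsAsFactors = FALSE)
      next_spot <- next_spot + n
    }
    spots <- if (length(spot_rows)) do.call(rbind, spot_rows)
    else data.frame(spot_id = character(0), cell_id = character(0),
                    frame = integer(0), x_um = numeric(0), y_um = numeric(0),
                    z_um = numeric(0), gfp = numeric(0),
                    tdtomato = numeric(0), stringsAsFactors = FALSE)
    links <- list()
    for (ci in seq_along(cells)) {
      ce <- cells[[ci]]
      ids <- spot_rows[[ci]]$spot_id
      if (length(ids) > 1L)
        links[[length(links) + 1L]] <-
          data.frame(source_spot_id = ids[-length(ids)],
                     target_spot_id = ids[-1L], stringsAsFactors = FALSE)
      if (!is.null(ce$parent)) {
        pi <- which(vapply(cells, function(x) x$id, "") == ce$parent)
        links[[length(links) + 1L]] <- data.frame(
          source_spot_id = utils::tail(spot_rows[[pi]]$spot_id, 1L),
          target_spot_id = ids[1L], stringsAsFactors = FALSE)
      }
    }
    links <- if (length(links)) do.call(rbind, links)
    else data.frame(source_spot_id = character(0),
                    target_spot_id = character(0))
    leaf <- vapply(cells, function(x) x$leaf, TRUE)
    fate_true <- vapply(cells, function(x) x$fate, "")
    masked <- leaf & stats::runif(length(cells)) < config$undetermined_frac
    fates <- data.frame(
      cell_id = vapply(cells, function(x) x$id, "")[leaf],
      fate = ifelse(masked, "UNDETERMINED", fate_true)[leaf],
      stringsAsFactors = FALSE)
    t_bg <- seq(0, total_f * dt, by = config$background_sample_interval_min)
    meta <- movie_meta(
      movie_id, frame_interval_min = dt,
      background_samples = data.frame(
        t_min = t_bg,
        intensity = bg_true(t_bg) +
          stats::rnorm(length(t_bg), 0, config$gfp_background[["noise_sd"]])),
      gfp_max = if (nrow(spots)) max(spots$gfp))
    truth <- data.frame(
      cell_id = vapply(cells, function(x) x$id, ""),
      fate_true = fate_true,
      onset_local_min = vapply(cells, function(x) x$onset %||% NA_real_, 0),
      w_pair = vapply(cells, function(x) x$w_pair, 0),
      potency = vapply(cells, function(x) x$potency, ""),
      leaf = leaf, stringsAsFactors = FALSE)
    movies[[mv]] <- list(spots = spots, links = links, fates = fates,
                         meta = meta, truth = truth,
                         start_min = start_m)
  }
  structure(list(movies = movies, config = config, seed = as.integer(seed)),
            class = "synthetic_embryo")
}

#' @export
print.synthetic_embryo <- function(x, ...) {
  cat(sprintf("<synthetic_embryo> %d movie(s), seed %d\n",
              length(x$movies), x$seed))
  invisible(x)
}

#' Assemble the forests of a synthetic embryo
#'
#' @param sim a `synthetic_embryo`.
#' @param use_fates attach the (possibly masked) fate annotations.
#' @return List of `lineage_forest`, one per movie.
#' @export
as_forests <- function(sim, use_fates = TRUE) {
  lapply(sim$movies, function(m)
    assemble_forest(m$spots, m$links, m$meta,
                    fates = if (use_fates) m$fates))
}
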