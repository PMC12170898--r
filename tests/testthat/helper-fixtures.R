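# Shared fixtures built in code.

# Minimal forest: one mother dividing once, straight tracks.
tiny_forest <- function() {
  spots <- data.frame(
    spot_id = as.character(1:9),
    cell_id = c(rep("m", 3), rep("d1", 3), rep("d2", 3)),
    frame = c(0:2, 3:5, 3:5),
    x_um = c(0, 1, 2, 3, 4, 5, 3, 2, 1),
    y_um = c(0, 0, 0, 1, 1, 1, -1, -1, -1),
    z_um = 0, gfp = 10, tdtomato = 100)
  links <- data.frame(
    source_spot_id = as.character(c(1, 2, 4, 5, 7, 8, 3, 3)),
    target_spot_id = as.character(c(2, 3, 5, 6, 8, 9, 4, 7)))
  assemble_forest(spots, links, movie_meta("tiny"),
                  fates = data.frame(cell_id = c("d1", "d2"),
                                     fate = c("LV_AVC", "LV_AVC")))
}

# A small fast simulation config for structural tests.
small_sim_config <- function(...) {
  sim_config(n_movies = 1, frames_per_movie = 250, movie_start_min = 0,
             n_mothers_per_fate = c(LV_AVC = 4, ATRIAL = 0, ENDOCARDIUM = 3,
                                    PERICARDIUM = 2, EXEM = 2,
                                    ENDOTHELIAL_LIKE = 0, MESO_GFP_NEG = 1),
             birth_time_windows = list(LV_AVC = c(0, 100),
                                       ENDOCARDIUM = c(0, 100),
                                       PERICARDIUM = c(0, 100),
                                       EXEM = c(0, 100),
                                       MESO_GFP_NEG = c(0, 100)),
             cycle_length = c(mean_min = 200, sd_min = 40),
             max_generations = 3,
             gfp_onset = list(LV_AVC = c(mean_min = 350, sd_min = 40)),
             undetermined_frac = 0, ...)
}

# Config for the sister-correlation contrast experiments (criterion-scale).
contrast_sim_config <- function(sister_corr_uni = 0.9, sister_corr_bi = 0.1) {
  sim_config(
    n_movies = 1, frames_per_movie = 300, movie_start_min = 0,
    n_mothers_per_fate = c(LV_AVC = 10, ATRIAL = 0, ENDOCARDIUM = 5,
                           PERICARDIUM = 5, EXEM = 0, ENDOTHELIAL_LIKE = 0,
                           MESO_GFP_NEG = 0),
    p_bipotent = 0.5, max_generations = 2,
    birth_time_windows = list(LV_AVC = c(0, 60), ENDOCARDIUM = c(0, 60),
                              PERICARDIUM = c(0, 60)),
    cycle_length = c(mean_min = 240, sd_min = 50),
    gfp_onset = list(LV_AVC = c(mean_min = 400, sd_min = 60)),
    sister_corr_uni = sister_corr_uni, sister_corr_bi = sister_corr_bi,
    undetermined_frac = 0)
}

# Split a pair table into uni/bi log-DTW groups.
logdtw_groups <- function(pt) {
  list(uni = pt$log_dtw[!is.na(pt$category) &
                          pt$category %in% c("Uni", "UniExEm") &
                          !is.na(pt$log_dtw)],
       bi = pt$log_dtw[!is.na(pt$category) &
                         pt$category %in% c("Bi", "BiExEm") &
                         !is.na(pt$log_dtw)])
}
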