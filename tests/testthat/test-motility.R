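straight_cell_forest <- function(speed_um_min = 1, frames = 0:100,
                                 interval = 2) {
  n <- length(frames)
  spots <- data.frame(spot_id = as.character(seq_len(n)), cell_id = "c",
                      frame = frames,
                      x_um = frames * interval * speed_um_min,
                      y_um = 0, z_um = 0, gfp = 1, tdtomato = 1)
  assemble_forest(spots, data.frame(source_spot_id = character(0),
                                    target_spot_id = character(0)),
                  movie_meta("m", frame_interval_min = interval))
}

test_that("interval speed is path length over time in each aligned bin", {
  f <- straight_cell_forest(1, 0:50)  # 100 min at 1 um/min
  sp <- interval_speed(f)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$speed_um_min, 1)
  expect_equal(sp$duration_in_bin_min, 100)
  # stationary cell
  g <- straight_cell_forest(0, 0:50)
  expect_equal(interval_speed(g)$speed_um_min, 0)
  # 40-min rule: a 30-min sliver in a second bin is dropped
  h <- straight_cell_forest(1, 0:165)  # 330 min: 300 in bin 1, 30 in bin 2
  sph <- interval_speed(h)
  expect_equal(sph$bin, 1L)
  # rigid motion invariance
  r <- straight_cell_forest(1, 0:50)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  pos <- as.matrix(r$spots[, c("x_um", "y_um", "z_um")]) %*% t(R)
  r$spots[, c("x_um", "y_um", "z_um")] <- sweep(pos, 2, c(5, -3, 11), `+`)
  expect_equal(interval_speed(r)$speed_um_min, 1, tolerance = 1e-12)
  # alignment offset moves the bin
  f$meta$alignment_offset_min <- 300
  expect_equal(interval_speed(f)$bin, 2L)
})

test_that("tortuosity geometry: straight, perpendicular, loop, stationary", {
  # straight path -> exactly 1 in every window
  f <- straight_cell_forest(1, 0:100)
  r <- tortuosity(f, "c")
  expect_identical(r$mean_tortuosity, 1)
  expect_true(all(r$local_values == 1))
  # perpendicular equal legs within one 50-min window -> sqrt(2)/2
  # 2.5-min frames: 21 frames = 50 min, leg switch at frame 10
  frames <- 0:72
  xs <- pmin(frames, 10) * 2.5
  ys <- pmax(frames - 10, 0) * 2.5
  spots <- data.frame(spot_id = as.character(frames + 1), cell_id = "c",
                      frame = frames, x_um = xs, y_um = ys, z_um = 0,
                      gfp = 1, tdtomato = 1)
  g <- assemble_forest(spots, data.frame(source_spot_id = character(0),
                                         target_spot_id = character(0)),
                       movie_meta("m", frame_interval_min = 2.5))
  rg <- tortuosity(g, "c")
  expect_equal(rg$local_values[1], sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(rg$local_values[-1], rep(1, length(rg$local_values) - 1))
  # closed loop inside each window -> ~0
  lf <- worked_example_forest()
  rl <- tortuosity(lf, "B_M")
  expect_lt(rl$mean_tortuosity, 0.05)
  # stationary window counts as straight
  s <- straight_cell_forest(0, 0:100)
  expect_equal(tortuosity(s, "c")$mean_tortuosity, 1)
  # cells under 3 h are excluded
  short <- straight_cell_forest(1, 0:80)  # 160 min
  expect_null(tortuosity(short, "c"))
  # bounded by 1, invariant to uniform scaling
  set.seed(1)
  frames <- 0:120
  pos <- apply(matrix(rnorm(3 * 121), ncol = 3), 2, cumsum)
  mk <- function(scale) {
    sp <- data.frame(spot_id = as.character(frames + 1), cell_id = "c",
                     frame = frames, x_um = scale * pos[, 1],
                     y_um = scale * pos[, 2], z_um = scale * pos[, 3],
                     gfp = 1, tdtomato = 1)
    assemble_forest(sp, data.frame(source_spot_id = character(0),
                                   target_spot_id = character(0)),
                    movie_meta("m"))
  }
  r1 <- tortuosity(mk(1), "c"); r5 <- tortuosity(mk(5), "c")
  expect_true(all(r1$local_values <= 1))
  expect_equal(r1$local_values, r5$local_values, tolerance = 1e-12)
})

test_that("final partial tortuosity window follows the 25-min rule", {
  # 270 min: 5 full windows + 20-min remnant (dropped)
  f <- straight_cell_forest(1, 0:135)
  expect_equal(length(tortuosity(f, "c")$local_values), 5L)
  # 280 min: 5 full windows + 30-min remnant (kept)
  g <- straight_cell_forest(1, 0:140)
  expect_equal(length(tortuosity(g, "c")$local_values), 6L)
})

test_that("contact threshold derivation is the sample mean", {
  expect_equal(derive_contact_threshold(c(12, 14)), 13)
  expect_equal(derive_contact_threshold(13), 13)
  expect_error(derive_contact_threshold(numeric(0)), "sample")
})

test_that("contact ratios match the worked example's closed forms", {
  f <- worked_example_forest()
  ct <- contact_ratio(f)
  get <- function(a) ct[ct$cell_a == a, ]
  # separation 10 + 0.04k um over k = 0..150: below 13 for k < 75
  expect_equal(get("A_D1")$ratio, 75 / 151)
  expect_equal(get("A_D1")$contact_min, 150)
  expect_equal(get("A_D1")$coexist_min, 302)
  # gen-2 pair: sqrt(k^2 + (4-k)^2) < 13 for k <= 10
  expect_equal(get("A_D11")$ratio, 11 / 121)
  expect_equal(get("A_D11")$generation, 2L)
  # perpendicular movers: k*sqrt(2) < 13 for k <= 9
  expect_equal(get("B_D1")$ratio, 10 / 150)
  expect_true(all(ct$contact_at_birth))
  expect_equal(contact_retention_rate(ct)$rate, 1)
  expect_equal(contact_retention_rate(ct)$n, 3L)
  # all-beyond pair: shift A_D2 far away
  g <- f
  g$spots$y_um[g$spots$cell_id == "A_D2"] <- -100
  ctg <- contact_ratio(g)
  expect_equal(ctg$ratio[ctg$cell_a == "A_D1"], 0)
  expect_false(ctg$contact_at_birth[ctg$cell_a == "A_D1"])
  # monotone non-decreasing in the threshold
  ct20 <- contact_ratio(f, threshold_um = 20)
  expect_true(all(ct20$ratio >= ct$ratio))
  # 16-h window truncation and 4-h exclusion
  ct_w <- contact_ratio(f, window_min = 300)
  # frames 102..300 at 2 min = 100 frame samples
  expect_equal(ct_w$coexist_min[ct_w$cell_a == "A_D1"], 200)
  expect_equal(nrow(contact_ratio(f, min_cycle_min = 500)), 0L)
})

test_that("fate-specific speed regimes are realised by the generator", {
  cfg <- small_sim_config()
  sim <- generate_embryo(cfg, seed = 31)
  f <- as_forests(sim)[[1]]
  sp <- interval_speed(f)
  tr <- sim$movies[[1]]$truth
  sp$fate_true <- tr$fate_true[match(sp$cell_id, tr$cell_id)]
  prof <- default_speed_profile()
  agg <- aggregate(speed_um_min ~ fate_true, sp[sp$bin == 1, ], mean)
  # realised bin-1 means sit near the configured profile
  for (i in seq_len(nrow(agg))) {
    cfg_speed <- prof[agg$fate_true[i], 1]
    expect_lt(abs(agg$speed_um_min[i] - cfg_speed), 0.08)
  }
  # ExEm slowest in the first interval, as configured
  expect_equal(agg$fate_true[which.min(agg$speed_um_min)], "EXEM")
})
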