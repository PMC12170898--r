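make_axis <- function() axis_spec("AP", c(0, 0, 0), c(100, 0, 0))

test_that("clone spread is the projected range over the axis length", {
  # direct geometry on a handmade clone of three GFP+ cells
  mk_clone <- function(xs, gfps = rep(400, length(xs))) {
    n <- length(xs)
    spots <- do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(spot_id = as.character(1000 * i + 0:150),
                 cell_id = paste0("c", i), frame = 0:150,
                 x_um = xs[i], y_um = 0, z_um = 0, gfp = gfps[i],
                 tdtomato = 1)))
    # fake lineage: independent roots except c2, c3 are children of c1
    links <- data.frame(
      source_spot_id = c("1150", "1150"),
      target_spot_id = c("2000", "3000"))
    spots$frame[spots$cell_id == "c2"] <- 151:301
    spots$frame[spots$cell_id == "c3"] <- 151:301
    meta <- movie_meta("sp", background_samples = data.frame(
      t_min = 0, intensity = 100), gfp_max = 400)
    assemble_forest(spots, links, meta,
                    fates = data.frame(cell_id = c("c2", "c3"),
                                       fate = "LV_AVC"))
  }
  f <- mk_clone(c(20, 20, 30))
  th <- list(multiplier = 1.5, background = fit_background(
    f$meta$background_samples), gfp_max = 400)
  class(th) <- "threshold_model"
  sr <- clone_axis_spread(f, "c1", make_axis(), th, at_time = 500,
                          min_cycle_age_min = 0)
  expect_equal(sr$fraction, 0.1)
  expect_equal(sr$n_cells, 2L)  # c1 no longer alive at t = 500
  # the 4-h-into-cycle filter: daughters are only 198 min old at t = 500
  expect_error(clone_axis_spread(f, "c1", make_axis(), th, at_time = 500),
               "empty-clone")
  # single GFP+ cell -> 0
  f1 <- mk_clone(c(20, 20, 30), gfps = c(400, 400, 80))
  sr1 <- clone_axis_spread(f1, "c1", make_axis(), th, at_time = 500,
                           min_cycle_age_min = 0)
  expect_equal(sr1$fraction, 0)
  # cells at both endpoints -> 1 (use positions 0 and 100)
  g <- mk_clone(c(50, 0, 100))
  sr2 <- clone_axis_spread(g, "c1", make_axis(), th, at_time = 500,
                           min_cycle_age_min = 0)
  expect_equal(sr2$fraction, 1)
  # rigid translation of clone + axis leaves the fraction unchanged
  h <- mk_clone(c(20, 20, 30))
  h$spots$x_um <- h$spots$x_um + 55
  h$spots$y_um <- h$spots$y_um - 12
  ax2 <- axis_spec("AP", c(55, -12, 0), c(155, -12, 0))
  sr3 <- clone_axis_spread(h, "c1", ax2, th, at_time = 500,
                           min_cycle_age_min = 0)
  expect_equal(sr3$fraction, sr$fraction, tolerance = 1e-12)
})

test_that("family distance samples reproduce the worked example", {
  f <- worked_example_forest()
  fd <- family_distance_samples(f, "A_M")
  expect_equal(fd$timepoint, c("T0", "T1", "T2"))
  expect_equal(fd$kind, c("heterotypic", "heterotypic", "homotypic"))
  expect_equal(fd$distance[fd$timepoint == "T0"], 10.36, tolerance = 1e-9)
  expect_equal(fd$distance[fd$timepoint == "T1"], 16, tolerance = 1e-9)
  expect_equal(fd$distance[fd$timepoint == "T2"], sqrt(120^2 + 116^2),
               tolerance = 1e-9)
  # T0 offset is configurable (the 10-min convention)
  fd10 <- family_distance_samples(f, "A_M", t0_offset_min = 10)
  expect_equal(fd10$t_min[fd10$timepoint == "T0"], 110)
  # sisters at 3-4-5 and identical positions
  expect_equal(midpoint_distance(matrix(c(0, 0, 0), 1),
                                 matrix(c(3, 4, 0), 1)), 5)
  expect_equal(midpoint_distance(matrix(c(1, 2, 3), 1),
                                 matrix(c(1, 2, 3), 1)), 0)
})

test_that("midpoint distance equals the brute-force centroid computation", {
  set.seed(4)
  for (k in 1:20) {
    a <- matrix(rnorm(3 * sample(1:4, 1)), ncol = 3)
    b <- matrix(rnorm(3 * sample(1:4, 1)), ncol = 3)
    brute <- sqrt(sum((apply(a, 2, mean) - apply(b, 2, mean))^2))
    expect_equal(midpoint_distance(a, b), brute, tolerance = 1e-12)
  }
  expect_error(midpoint_distance(matrix(numeric(0), 0, 3),
                                 matrix(0, 1, 3)), "side")
})

test_that("distances are symmetric and satisfy the triangle inequality", {
  set.seed(7)
  for (k in 1:25) {
    p <- matrix(rnorm(9), 3)
    d12 <- vec <- function(i, j) sqrt(sum((p[i, ] - p[j, ])^2))
    expect_equal(vec(1, 2), vec(2, 1))
    expect_lte(vec(1, 3), vec(1, 2) + vec(2, 3) + 1e-12)
  }
})

test_that("homotypic distances are smaller than heterotypic under fate-linked motion", {
  cfg <- contrast_sim_config()
  hom <- het <- c()
  for (s in 1:5) {
    f <- as_forests(generate_embryo(cfg, seed = 100 + s))[[1]]
    fd <- do.call(rbind, lapply(forest_roots(f), function(r)
      family_distance_samples(f, r)))
    fd <- fd[fd$timepoint %in% c("T1", "T2"), ]
    hom <- c(hom, fd$distance[fd$kind == "homotypic"])
    het <- c(het, fd$distance[fd$kind == "heterotypic"])
  }
  expect_gt(length(hom), 10)
  expect_gt(length(het), 10)
  expect_lt(mean(hom), mean(het))
})

test_that("sister myocyte dispersion summarises same-family GFP+ pairs", {
  f <- worked_example_forest()
  th <- find_threshold(f, fit_background(f$meta$background_samples))
  # end of migration = 336 min (frame 168): D11/D12 not yet born,
  # D1 is the only GFP+ myocyte -> no pair at END, pairs exist at HT
  end_res <- suppressWarnings(
    sister_myocyte_dispersion(f, th, stage = "end_migration"))
  expect_equal(end_res$n, 0L)
  ht <- sister_myocyte_dispersion(f, th, stage = "heart_tube")
  expect_equal(ht$n, 1L)
  # D11 at (322, 7), D12 at (202, 123) at t = 644
  expect_equal(ht$mean, sqrt(120^2 + 116^2), tolerance = 1e-9)
})

test_that("potency classification counts determined fates and restriction", {
  f <- worked_example_forest()
  pa <- classify_potency(f, "A_M")
  expect_equal(pa$potency, "bipotent")
  expect_equal(pa$restriction_generation, 1L)
  pb <- classify_potency(f, "B_M")
  expect_equal(pb$potency, "bipotent")
  # all leaves same fate -> uni-fated, restriction 0
  g <- f
  g$cells$fate[g$cells$cell_id == "A_D2"] <- "LV_AVC"
  expect_equal(classify_potency(g, "A_M")$potency, "uni-fated")
  expect_equal(classify_potency(g, "A_M")$restriction_generation, 0L)
  # an undetermined leaf blocks the call
  h <- f
  h$cells$fate[h$cells$cell_id == "A_D2"] <- "UNDETERMINED"
  expect_equal(classify_potency(h, "A_M")$potency, "undetermined")
  # invariance to leaf ordering
  sim <- generate_embryo(small_sim_config(p_bipotent = 0.6), seed = 13)
  f2 <- as_forests(sim)[[1]]
  perm <- sample(nrow(f2$cells))
  f3 <- f2; f3$cells <- f3$cells[perm, ]
  for (r in forest_roots(f2))
    expect_equal(classify_potency(f2, r), classify_potency(f3, r))
})
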