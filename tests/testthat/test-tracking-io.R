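test_that("minimal inputs assemble into valid forests", {
  # one spot, no links
  f1 <- assemble_forest(
    data.frame(spot_id = "1", cell_id = "c", frame = 0, x_um = 1, y_um = 2,
               z_um = 3, gfp = 4, tdtomato = 5),
    data.frame(source_spot_id = character(0), target_spot_id = character(0)),
    movie_meta("m"))
  expect_equal(unname(count_forest(f1)), c(1L, 0L))
  expect_equal(f1$cells$generation_label, "M")
  expect_equal(nrow(validate_forest(f1)), 0L)
  # one division
  f2 <- tiny_forest()
  expect_equal(unname(count_forest(f2)), c(1L, 2L))
  expect_setequal(f2$cells$generation_label, c("M", "D1", "D2"))
  expect_equal(nrow(validate_forest(f2)), 0L)
  # d1 (first spot id 4) gets suffix 1
  expect_equal(f2$cells$generation_label[f2$cells$cell_id == "d1"], "D1")
})

test_that("format and integrity errors are reported with the offender", {
  sp <- data.frame(spot_id = "1", cell_id = "c", frame = 0, x_um = 0,
                   y_um = 0, z_um = 0, gfp = 0, tdtomato = 0)
  expect_error(
    assemble_forest(sp, data.frame(source_spot_id = "1",
                                   target_spot_id = "99"), movie_meta("m")),
    "99")
  tf <- tempfile(fileext = ".csv")
  utils::write.csv(sp[, -3], tf, row.names = FALSE)
  lf <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(source_spot_id = character(0),
                              target_spot_id = character(0)), lf,
                   row.names = FALSE)
  expect_error(read_tracking_table(tf, lf, movie_meta("m")), "frame")
})

test_that("non-binary divisions are rejected and reported", {
  spots <- data.frame(spot_id = as.character(1:4),
                      cell_id = c("m", "a", "b", "c"), frame = c(0, 1, 1, 1),
                      x_um = 0, y_um = 0, z_um = 0, gfp = 0, tdtomato = 0)
  links <- data.frame(source_spot_id = "1", target_spot_id = as.character(2:4))
  expect_error(assemble_forest(spots, links, movie_meta("m")), "0,2")
})

test_that("validate_forest flags injected violations", {
  f <- tiny_forest()
  # 3 children
  f$cells <- rbind(f$cells, data.frame(cell_id = "d3", parent = "m",
                                       generation_label = NA, fate = NA))
  f$spots <- rbind(f$spots,
                   data.frame(spot_id = "10", cell_id = "d3", frame = 3,
                              t_min = 6, x_um = 0, y_um = 0, z_um = 0,
                              gfp = 1, tdtomato = 1))
  rep <- validate_forest(f)
  expect_true("binary_division" %in% rep$rule)
  # time inversion
  g <- tiny_forest()
  g$spots$frame[g$spots$spot_id == "2"] <- 0
  g$spots$t_min[g$spots$spot_id == "2"] <- 0
  expect_true("monotone_frames" %in% validate_forest(g)$rule)
})

test_that("generation labels enumerate the binary tree deterministically", {
  cfg <- small_sim_config()
  f <- as_forests(generate_embryo(cfg, seed = 3))[[1]]
  labs <- f$cells$generation_label
  # 3-generation trees produce at most 7 labels per tree, all unique per tree
  for (r in f$cells$cell_id[is.na(f$cells$parent)]) {
    ids <- f$cells$cell_id[is.na(f$cells$parent) & f$cells$cell_id == r]
    sub <- labs[startsWith(f$cells$cell_id, sub("_M$", "", r))]
    expect_equal(anyDuplicated(sub), 0L)
  }
  expect_true(all(labs %in% c("M", "D1", "D2", "D11", "D12", "D21", "D22")))
  # permutation invariance to row order
  sim <- generate_embryo(cfg, seed = 3)$movies[[1]]
  perm <- sample(nrow(sim$spots))
  f2 <- assemble_forest(sim$spots[perm, ], sim$links, sim$meta, sim$fates)
  l1 <- setNames(f$cells$generation_label, f$cells$cell_id)
  l2 <- setNames(f2$cells$generation_label, f2$cells$cell_id)
  expect_equal(l1[sort(names(l1))], l2[sort(names(l2))])
})

test_that("newick export matches the format and round-trips through ape", {
  f <- tiny_forest()
  # both daughters tracked 2 frames = 4 min
  expect_equal(unname(export_newick(f)["m"]), "(D1:4,D2:4)M;")
  lone <- assemble_forest(
    data.frame(spot_id = "1", cell_id = "c", frame = 0, x_um = 0, y_um = 0,
               z_um = 0, gfp = 0, tdtomato = 0),
    data.frame(source_spot_id = character(0), target_spot_id = character(0)),
    movie_meta("m"))
  expect_equal(unname(export_newick(lone)), "M;")
  # random synthetic tree: parse(export(x)) recovers topology and durations
  f3 <- as_forests(generate_embryo(small_sim_config(), seed = 5))[[1]]
  nwk <- export_newick(f3)
  nwk <- nwk[grepl("(", nwk, fixed = TRUE)]
  for (root in names(nwk)[seq_len(min(3, length(nwk)))]) {
    tr <- ape::read.tree(text = nwk[[root]])
    expect_true(ape::is.binary(tr))
    all_labs <- c(tr$tip.label, tr$node.label)
    expect_true(all(grepl("^M$|^D[12]+$", all_labs)))
    # edge lengths equal tracked durations of this tree's cells
    tree_tag <- sub("_M$", "", root)
    in_tree <- startsWith(f3$cells$cell_id, paste0(tree_tag, "_"))
    life <- do.call(rbind, lapply(which(in_tree), function(i) {
      s2 <- cell_spots(f3, f3$cells$cell_id[i])
      data.frame(lab = f3$cells$generation_label[i],
                 dur = max(s2$t_min) - min(s2$t_min))
    }))
    child_lab <- all_labs[tr$edge[, 2]]
    m <- merge(data.frame(lab = child_lab, len = tr$edge.length), life,
               by = "lab")
    expect_gt(nrow(m), 0)
    expect_true(all(abs(m$len - m$dur) < 1e-6))
  }
})

test_that("write -> read round-trips a synthetic forest", {
  sim <- generate_embryo(small_sim_config(), seed = 9)
  f <- as_forests(sim)[[1]]
  d <- tempfile(); dir.create(d)
  paths <- file.path(d, c("s.csv", "l.csv", "f.csv"))
  write_tracking_table(f, paths[1], paths[2], paths[3])
  f2 <- read_tracking_table(paths[1], paths[2], f$meta, fates_path = paths[3])
  o1 <- order(f$cells$cell_id); o2 <- order(f2$cells$cell_id)
  expect_equal(f$cells[o1, ], f2$cells[o2, ], ignore_attr = TRUE)
  s1 <- f$spots[order(f$spots$cell_id, f$spots$frame), ]
  s2 <- f2$spots[order(f2$spots$cell_id, f2$spots$frame), ]
  expect_equal(s1$x_um, s2$x_um, tolerance = 1e-9)
  expect_equal(s1$gfp, s2$gfp, tolerance = 1e-9)
  expect_equal(s1$spot_id, s2$spot_id)
  # descendant count identity
  n <- count_forest(f)
  per_tree <- table(sub("_[MD][0-9]*$", "", f$cells$cell_id))
  expect_equal(unname(n[["n_descendants"]]), sum(per_tree - 1L))
})

test_that("column mapping adapts foreign schemas and long gaps split lives", {
  sim <- generate_embryo(small_sim_config(), seed = 2)$movies[[1]]
  sp <- sim$spots
  names(sp)[names(sp) == "x_um"] <- "POSITION_X"
  d <- tempfile(); dir.create(d)
  utils::write.csv(sp, file.path(d, "s.csv"), row.names = FALSE)
  utils::write.csv(sim$links, file.path(d, "l.csv"), row.names = FALSE)
  f <- read_tracking_table(file.path(d, "s.csv"), file.path(d, "l.csv"),
                           sim$meta, column_map = c(x_um = "POSITION_X"))
  expect_equal(nrow(validate_forest(f)), 0L)
  # cut a 10-frame hole into one leaf cell -> split with warning
  leaf <- sim$fates$cell_id[1]
  sp2 <- sim$spots
  sel <- sp2$cell_id == leaf
  frames <- sort(sp2$frame[sel])
  if (length(frames) > 30) {
    hole <- frames[10:19]
    drop <- sel & sp2$frame %in% hole
    sp2 <- sp2[!drop, ]
    keep_links <- !(sim$links$source_spot_id %in% sim$spots$spot_id[drop] |
                      sim$links$target_spot_id %in% sim$spots$spot_id[drop])
    expect_warning(
      f2 <- assemble_forest(sp2, sim$links[keep_links, ], sim$meta),
      "split")
    expect_true(paste0(leaf, ".s2") %in% f2$cells$cell_id)
  }
})
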