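#' Deterministic worked-example dataset
#'
#' A tiny two-family, three-generation movie built from closed-form tracks
#' so that every downstream metric has a hand-computable expected value:
#' family A holds a bipotent mother whose D1 branch differentiates to
#' LV/AVC myocytes (GFP step at frame 100, i.e. 200 min) while D2 stays
#' GFP-negative mesoderm and drifts away at a constant rate; family B holds
#' a bipotent endocardium/ExEm mother moving on a closed circle (windowed
#' tortuosity exactly 0) whose endocardial daughter peaks at 1.5x the flat
#' background of 100. Calling it twice gives identical output.
#'
#' @return List with `spots`, `links`, `fates`, `meta` in the canonical
#'   tracking schema.
#' @export
generate_worked_example <- function() {
  dt <- 2
  cells <- list()
  add <- function(id, frames, x, y, z, gfp, parent = NA_character_,
                  fate = NA_character_) {
    n <- length(frames)
    cells[[length(cells) + 1L]] <<- list(
      id = id, parent = parent, fate = fate,
      df = data.frame(cell_id = id, frame = frames,
                      x_um = rep_len(x, n), y_um = rep_len(y, n),
                      z_um = rep_len(z, n), gfp = rep_len(gfp, n),
                      tdtomato = 500, stringsAsFactors = FALSE))
  }
  # --- family A ------------------------------------------------------------
  f <- 0:50
  add("A_M", f, x = f, y = 0, z = 0, gfp = 80)
  f <- 51:201
  add("A_D1", f, x = f, y = 5, z = 0, gfp = ifelse(f >= 100, 400, 80),
      parent = "A_M")
  f <- 202:322
  add("A_D11", f, x = f, y = 7, z = 0, gfp = 400, parent = "A_D1",
      fate = "LV_AVC")
  add("A_D12", f, x = 202, y = 3 + (f - 202), z = 0, gfp = 400,
      parent = "A_D1", fate = "LV_AVC")
  f <- 51:301
  add("A_D2", f, x = f, y = -5 - 0.04 * (f - 51), z = 0, gfp = 80,
      parent = "A_M", fate = "MESO_GFP_NEG")
  # --- family B ------------------------------------------------------------
  f <- 0:100
  add("B_M", f, x = 300 + 10 * cos(2 * pi * f / 25),
      y = 300 + 10 * sin(2 * pi * f / 25), z = 50, gfp = 80)
  f <- 101:250
  add("B_D1", f, x = 300 + (f - 101), y = 300, z = 50,
      gfp = ifelse(f == 200, 150, 120), parent = "B_M",
      fate = "ENDOCARDIUM")
  add("B_D2", f, x = 300, y = 300 + (f - 101), z = 50, gfp = 90,
      parent = "B_M", fate = "EXEM")
  # --- tables --------------------------------------------------------------
  spot_blocks <- lapply(cells, `[[`, "df")
  n_per <- vapply(spot_blocks, nrow, 0L)
  first_id <- cumsum(c(0L, n_per[-length(n_per)]))
  spots <- do.call(rbind, spot_blocks)
  spots <- cbind(spot_id = as.character(seq_len(nrow(spots))), spots)
  links <- list()
  for (i in seq_along(cells)) {
    ids <- as.character(first_id[i] + seq_len(n_per[i]))
    links[[length(links) + 1L]] <-
      data.frame(source_spot_id = ids[-length(ids)],
                 target_spot_id = ids[-1L], stringsAsFactors = FALSE)
    p <- cells[[i]]$parent
    if (!is.na(p)) {
      j <- which(vapply(cells, `[[`, "", "id") == p)
      links[[length(links) + 1L]] <- data.frame(
        source_spot_id = as.character(first_id[j] + n_per[j]),
        target_spot_id = ids[1L], stringsAsFactors = FALSE)
    }
  }
  fates <- do.call(rbind, lapply(
    Filter(function(c) !is.na(c$fate), cells),
    function(c) data.frame(cell_id = c$id, fate = c$fate,
                           stringsAsFactors = FALSE)))
  meta <- movie_meta("WE", frame_interval_min = dt,
                     background_samples = data.frame(
                       t_min = c(0, 650), intensity = c(100, 100)),
                     gfp_max = 400)
  list(spots = spots, links = do.call(rbind, links), fates = fates,
       meta = meta)
}

#' Worked example as an assembled forest
#'
#' @return A `lineage_forest` built from [generate_worked_example()].
#' @export
worked_example_forest <- function() {
  we <- generate_worked_example()
  assemble_forest(we$spots, we$links, we$meta, fates = we$fates)
}
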