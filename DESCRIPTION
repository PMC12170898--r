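Package: lineagemotility
Title: Lineage-Aware Migration Analysis of Tracked Embryonic Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing manually tracked cell lineages from
    time-lapse light-sheet movies of gastrulating mouse embryos. Reads
    spot/link tracking tables, reconstructs binary lineage forests with
    generation labels and Newick export, calls cardiomyocyte differentiation
    from a GFP reporter against an interpolated background threshold, aligns
    movies on differentiation timing, and quantifies clone dispersion,
    homotypic/heterotypic distances, speed, tortuosity and sister-cell
    contact. Sister-trajectory similarity is measured by slope-constrained
    (symmetric, P = 1) dynamic time warping with permutation inference on
    pooled log distances, and a seeded synthetic-embryo generator provides
    tracking data with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
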