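# lineagemotility

Lineage-aware migration analysis for manually tracked cells in time-lapse
light-sheet movies of gastrulating mouse embryos.

During heart development, early mesodermal progenitors migrate long
distances before differentiating into left-ventricle/atrioventricular-canal
(LV/AVC) or atrial myocytes, endocardium, pericardium, extraembryonic
mesoderm (ExEm) or endothelial-like cells. A central question is whether a
progenitor's fate is coupled to how its daughters migrate: do uni-fated
progenitors produce daughter cells with more similar, more cohesive
trajectories than bipotent ones? This package implements the full
quantitative chain needed to answer that question from tracking exports:

- **Tracking IO** — read spot/link CSV tables (MaMuT-style exports),
  assemble cell lives into binary lineage forests with generation labels
  (M, D1, D2, D11, ...), validate structural invariants, export Newick
  trees with cell-cycle branch lengths.
- **Differentiation calling** — normalise the cTnnT-2a-eGFP reporter per
  movie, interpolate background intensity samples linearly, and set the
  positivity threshold at the *lowest multiplier* `m` of the background
  that classifies every endocardial cell as GFP-negative:
  `m = (1 + 1e-6) * max(gfp / background(t))` over endocardial spots.
  A cell differentiates at its first (optionally persistent) exceedance of
  `m * background(t)`. Movies are temporally aligned on myocyte class mean
  differentiation times; the migration period ends at the mean LV/AVC
  (or atrial) differentiation time.
- **Lineage metrics** — clone spread `d/D` along user-supplied anatomical
  axes, homotypic/heterotypic distances at T0/T1/T2, midpoint distances,
  sister-myocyte dispersion, and progenitor potency (uni-fated, bipotent,
  tripotent) with the generation of fate restriction.
- **Motility** — mean speed in aligned 5-hour intervals (path length /
  time, dropping records under 40 min per bin), windowed tortuosity
  (straight-line / path distance in 50-min windows, averaged; cells under
  3 h excluded), and sister contact ratios (fraction of coexistence within
  the first 16 aligned hours spent closer than 13 um).
- **Trajectory similarity** — slope-constrained dynamic time warping with
  the symmetric P = 1 (Sakoe–Chiba `symmetricP1`) step pattern:

  ```
  g(1,1) = d(1,1)
  g(i,j) = min( g(i-1,j-2) + 2 d(i,j-1) + d(i,j),
                g(i-1,j-1) + 2 d(i,j),
                g(i-2,j-1) + 2 d(i-1,j) + d(i,j) )
  ```

  with Euclidean local cost, applied to sister (and second-generation
  cousin) trajectories from the frame after division to the first
  re-division, truncated at migration end. Pairs are categorised Uni /
  UniExEm / Bi / BiExEm by the daughters' fates, and a permutation test on
  pooled log-DTW distances (difference of group means, one-sided, 100,000
  permutations by default) asks whether uni-fated progenitors produce more
  similar sister trajectories than bipotent ones.
- **Synthetic embryos** — a seeded generator of tracking tables with the
  statistical structure the analysis assumes (persistent random walks with
  fate-specific speed regimes, sister-heading coupling that depends on
  shared vs distinct fate, logistic GFP onsets over a drifting background,
  an endocardial intensity ceiling), so every stage is testable against
  known ground truth with no data download.

## Worked example

The package ships a deterministic two-family, three-generation movie whose
metrics have closed-form values (`generate_worked_example()`):

```r
library(lineagemotility)
f  <- worked_example_forest()
#> <lineage_forest> movie WE: 2 mother cells, 6 descendants, 1096 spots

th <- find_threshold(f, fit_background(f$meta$background_samples))
#> <threshold_model> multiplier 1.5 over interpolated background
mean_differentiation_time(f, "LV_AVC", th)
#> [1] 336

contact_ratio(f)[, c("cell_a", "cell_b", "generation", "ratio")]
#>   cell_a cell_b generation      ratio
#> 1  A_D11  A_D12          2 0.09090909
#> 2   A_D1   A_D2          1 0.49668874
#> 3   B_D1   B_D2          1 0.06666667

pair_dtw_table(f)[, c("cell_a", "cell_b", "category", "log_dtw")]
#>   cell_a cell_b category   log_dtw
#> 1  A_D11  A_D12      Uni  9.895884
#> 2   A_D1   A_D2       Bi  8.272826
#> 3   B_D1   B_D2   BiExEm 10.360081

classify_potency(f, "A_M")$potency
#> [1] "bipotent"
```

The endocardial daughter peaks at exactly 1.5x the flat background of 100,
so the calibrated multiplier is 1.5; the LV/AVC cells cross the threshold
at 200, 404 and 404 min, giving the 336-min class mean; sisters A_D1/A_D2
separate at 0.02 um/min from an initial 10 um, staying under 13 um for 75
of 151 coexistence frames (ratio 0.497). `run_pipeline()` chains all
stages on real or simulated movies and writes tidy CSVs plus a JSON
summary; `plot_reports()` renders the standard panels.

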