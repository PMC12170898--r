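---
title: "Methods: lineage-aware migration analysis of tracked embryonic cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lineage-aware migration analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lineagemotility)
```

## The analysis problem

Manually tracked light-sheet movies of gastrulating mouse embryos yield,
per movie, a table of spots (one detection of one cell per frame, 3-D
position in micrometres, reporter intensities) and a table of links that
chain spots into cell lives and connect mothers to daughters at divisions.
Frames are 2 min apart; lineages reach five generations. The analysis asks
how migratory behaviour relates to lineage and fate: when and where cells
differentiate (cTnnT-2a-eGFP reporter onset), how far clones spread, how
fast and how straight cells move as a function of fate and developmental
time, how long sister cells stay in contact, and — the central inference —
whether uni-fated progenitors produce daughters with more similar
migration paths than bipotent progenitors.

## Data model and invariants

A `lineage_forest` holds one movie's cells and spots. Invariants enforced
or checked by `validate_forest()`: divisions are strictly binary (0 or 2
children), frames are strictly increasing within a cell life, time equals
frame times the frame interval, positions are finite, intensities are
non-negative, ancestry is acyclic, and generation labels are consistent
with tree position. Labels follow the M / D1 / D2 / D11 ... convention;
since no biological ordering of daughters exists, the daughter with the
smaller first spot id takes suffix 1, which makes labelling deterministic
and invariant to input row order. Tracks may begin mid-movie (the tdTomato
label becomes detectable at different times); a cell's birth date is the
time of its first spot. Gaps of at most 5 frames inside a life are kept
(metrics interpolate linearly across them); longer gaps split the life
with a warning rather than inventing an unobserved bridge.

## Differentiation from reporter intensity

Background GFP is sampled at intervals through each movie; the background
model interpolates linearly between samples and extends constantly beyond
them (`fit_background()`). Constant extrapolation is the conservative
choice: extrapolating a fitted slope outside the sampled range can produce
negative or runaway backgrounds.

The positivity threshold is a single multiplier `m` of the interpolated
background, calibrated per movie as the *lowest* multiplier that leaves
every endocardial cell GFP-negative — endocardium never activates this
reporter, so it provides an in-movie negative control. On continuous data
the "lowest" multiplier is the supremum `max(gfp/background)` itself, so we
multiply by `1 + 1e-6` to make every endocardial spot strictly
sub-threshold; this epsilon is far below intensity quantisation and makes
the definition well-posed. Comparisons are performed on raw intensity
against `m * background(t)`; dividing both sides by the movie maximum
(`normalize_gfp()`) gives the identical calls, so the choice of raw versus
normalised units is a presentation convention, which we fix to the
ratio-to-background form.

A cell's differentiation time is its first tracked exceedance; the
optional `persistence_frames` parameter (default 1) requires a run of
consecutive supra-threshold frames and guards against single-frame blips
in noisier data. Movies are aligned by averaging, over the myocyte classes
present in both movies, the difference between reference and movie class
mean differentiation times, rounded to the frame grid. The averaging
estimator is our choice — only the principle (align on differentiation
timing of LV/AVC and inflow myocytes) is fixed by the design; offsets are
therefore reproducible but may differ by minutes from any other estimator.
Alignment is translation-equivariant: shifting a movie's clock by delta
shifts its offset by minus delta. "Migration end" is the aligned mean
LV/AVC differentiation time (atrial mean for atrial analyses).

## Spatial and motility metrics

*Clone spread.* Anatomical axes (AP, DV) are user-supplied landmark
segments — they are established from anatomy, not inferred from the data.
Eligible clone cells (GFP-positive, alive at the sampling time, at least
4 h into their cycle so short post-division displacements do not bias the
range) are projected onto the unit axis; the spread is the range of
projections over the axis length. Projections are clamped to the segment
for the reported fraction (guaranteeing a value in [0, 1]); the unclamped
range is returned alongside.

*Family distances.* T0 is 20 min after the mother's division (a 10-min
convention also circulates; `t0_offset_min` exposes it), T1 the last time
point before the daughters' next division, T2 the last time point at which
all granddaughters coexist, bounded by migration end. Distances are tagged
homotypic when both determined fates agree and heterotypic when they
differ; pairs with an undetermined side are dropped rather than guessed.

*Speed.* Per cell and aligned 5-h bin: path length over tracked time, each
step assigned to the bin containing its start. Records with under 40 min
of track in a bin are excluded — a cell's bin mean over a few frames is
dominated by localisation noise.

*Tortuosity.* Straight-line distance over path distance in consecutive
50-min windows from the start of the cell life, averaged. Cells under 3 h
are excluded; a trailing window under 25 min is dropped (half a window is
the natural cut between "too short to mean anything" and "keep"); a
stationary window (0/0) is defined as 1, reading "did not deviate from a
straight course" for a cell that did not move. Values are bounded by 1 and
invariant to rigid motion and uniform scaling.

*Contact.* The contact criterion (13 um by default) is the mean distance
of visually confirmed in-contact pairs. For generation-1 and -2 sister
pairs with cycles of at least 4 h, the inter-sister distance is evaluated
on the shared frame grid within the first 16 aligned hours; the contact
ratio is time below threshold over pair coexistence time. The coexistence
denominator is our resolution of an ambiguity — "total cell cycle length"
of one sister is asymmetric in the pair and can exceed the window;
coexistence is the only symmetric, well-defined choice. Contact at the
first coexistence frame defines the post-division retention rate.

## Trajectory similarity and inference

`dtw_distance()` implements the slope-constrained symmetric step pattern
(Sakoe–Chiba, slope window P = 1; the pattern called `symmetricP1`): each
diagonal step may be preceded by at most one off-diagonal move, cells
violating the constraint stay infeasible, `g(1,1)` is initialised to
`delta(1,1)`, and ties in backtracking break deterministically (diagonal
first, then the column-advancing composite). Lengths with `M > 2N - 1` are
globally infeasible and rejected. The implementation is pinned by an
independent top-down memoized recursion and, for tiny inputs, exhaustive
enumeration of all admissible warping paths; tests require agreement to
1e-9 relative error on 200 random pairs.

Sister trajectories run from the frame after the mother's division to the
last frame before the first sister re-divides, truncated at migration end;
second-generation analyses add the four cousin pairs. Cumulative
(unnormalised) cost is the reported distance — pairs are compared on a log
scale where the trajectory-length factor becomes an additive offset
shared within generations; `g/(N+M)` is available behind `normalize =
TRUE`. "log DTW" is the natural logarithm (the base is a display
convention; tests and inference are invariant to it). The per-step curve
averages cumulative cost at each of the first 40 warping-path steps, with
shorter paths dropping out; reading "steps" as trajectory frames instead
is available via `by = "frame"` since both readings are defensible.

The permutation test pools uni-fated and bipotent log distances, reshuffles
labels preserving group sizes, and compares the observed difference of
means (bipotent minus uni) against the null, one-sided per the stated
hypothesis that uni-fated sisters are more similar, with the add-one
correction. For small groups it switches to exhaustive enumeration, where
the p-value is exact. Mann–Whitney comparisons elsewhere delegate to
`stats::wilcox.test` (normal approximation with tie correction) except for
small samples, where exhaustive enumeration over rank assignments is used
because the standard exact path refuses ties.

## The synthetic embryo generator

`generate_embryo()` produces tracking tables with the statistical
structure the analysis assumes, so that every stage can be verified
against ground truth without any imaging data. Defaults emulate the study
conditions: 5 movies at 2-min frames, starts staggered by 74/0/239/373/626
min on the embryo clock (movie 2 the alignment reference), about 45
mothers per movie across the seven fate classes, lognormal cell cycles
(mean 600 min, sd 150), up to five generations, and fate-specific 5-h
speed regimes in which ExEm cells start slowest and accelerate,
endocardial and endothelial-like cells step up sharply in the 10–15 h
interval, and pericardial cells slow down (`default_speed_profile()`).

Trajectories are persistent random walks: headings evolve by per-fate
autocorrelation, and each sister's step heading mixes a shared pair
heading with its own (weight `sister_corr_uni` = 0.9 for same-fate pairs,
`sister_corr_bi` = 0.1 for distinct-fate pairs), plus a small constant
outward bias that separates pairs over time (largest for bipotent pairs).
The paths of real sisters are phenomenologically parallel or divergent;
this mixture is the simplest generative mechanism with a single
interpretable knob per condition. Step length is profile speed times
lognormal noise with mean one, so realised mean speeds equal the profile.
Initial sister separations are uniform on 3–19 um, spanning the 13-um
contact criterion so that a majority of pairs (10/16 in expectation) begin
in contact.

Myocyte GFP rises logistically (60 min from 2% to 98%; no functional form
is fixed by the biology, a logistic is the standard saturating onset) at a
per-family onset drawn from fate-specific distributions placed on the
embryo clock (LV/AVC 1300 min, atrial 1815 min, back-computed from the
per-movie local class means and start stagger). Differentiated myocyte
lineages stop dividing — differentiated cardiomyocytes exit the cycle in
this window — which keeps "first family crossing" an unbiased estimate of
onset. All reporter-negative traces sit strictly below `endo_margin`
(1.5) times the true linear background (level 100, drift 0.05/min), a
hard ceiling that makes the least-multiplier threshold identifiable;
background samples are taken as exact, since in practice they are averages
over large annotated regions (a noise knob exists for robustness
experiments; the threshold estimator inflates with the most-underestimated
background sample, so recovery to 1% presumes clean samples).

What the generator does *not* emulate: tissue mechanics and epithelial
folding, localisation error, z-attenuation of intensity, cell death,
asynchronous division resolution below the frame grid, and cousin-level
heading coupling. Passing tests therefore demonstrate correctness of the
measurement chain and the identifiability of the modelled effects, not
that real embryos satisfy the model.

## Problem sizes and numerical choices

Tests and the acceptance script run scaled-down simulations chosen to keep
the whole suite in minutes while leaving comfortable statistical margins:
contrast experiments use one movie, 300 frames, 20 mothers, 2 generations
(about 20 sister pairs per replicate, 100 replicates, 2000-permutation
tests); onset/speed recovery uses two movies of 700 frames and 41 mothers;
threshold recovery uses one movie of 250 frames. The permutation
calibration uses 500 null replicates of 30-vs-30 samples. Monte Carlo
permutation p-values carry the add-one correction, so their floor is
`1/(n_perm + 1)`; exact enumeration is used automatically below 200,000
label assignments.

## Known limitations

- The alignment estimator is one of several consistent with "align on
  differentiation timing"; offsets can differ by minutes between
  estimators, and downstream bin assignments inherit that uncertainty.
- Intensity is not corrected for imaging depth; dim deep cells can be
  called late or missed, exactly as in the source data.
- The contact ratio treats the inter-sister distance per frame sample;
  sub-frame contact changes are invisible.
- `clone_axis_spread` requires user landmarks; no automatic axis detection
  is attempted.
- Potency classification trusts leaf annotations; any undetermined leaf
  makes the mother undetermined rather than risking a wrong potency call.
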