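# rangebridge

Home-range estimation and estimator comparison for radio-telemetry
tracks, built around dynamic Brownian bridge movement models.

## The problem

Estimating an animal's home range from time-stamped relocations is a
core task in movement ecology, and the choice of estimator materially
changes the answer: minimum convex polygons (MCP) and fixed kernel
density estimators (KDE) ignore the time ordering of fixes, so they
trade off Type I errors (excluding used areas) against Type II errors
(including unused areas) in ways that depend on the bandwidth rule more
than on the animal. Movement-based estimators model the path itself.
The Brownian bridge movement model (BBMM) treats the track as a sequence
of conditional random walks ("bridges") between consecutive fixes, with
a motion variance σ²ₘ and a per-fix location error δ; the dynamic
variant (dBBMM) lets σ²ₘ change along the path, estimating it in
sliding windows with change-point model selection, so stopovers
(σ²ₘ → 0) and movement bouts (large σ²ₘ) are handled on their own
terms. This matters especially for animals — snakes are the archetype —
that alternate multi-day shelter stays with long exploratory moves.

`rangebridge` implements the whole comparison pipeline as a tidyverse-
style R package:

* **Track model** — tracks are tibbles (`animal_id`, `timestamp`, `x`,
  `y`, `error_sd`) in a projected metric CRS; CSV ingestion/validation,
  season labelling, movement summaries.
* **Estimators** — percent MCP; fixed KDE with h_ref, h_LSCV (closed-form
  pairwise criterion, with the classic boundary non-convergence detected
  and flagged), two-stage plug-in, and manual h; BBMM and dBBMM with
  leave-one-out likelihood estimation of σ²ₘ.
* **Bridge model** — for a bridge of duration `T` at fractional time α,
  the position density is an isotropic normal with per-axis variance
  `s(α) = T·α·(1−α)·σ²ₘ + (1−α)²·δ₀² + α²·δ₁²`.
* **Dynamic profile** — sliding window (default 11 fixes) with one
  candidate breakpoint per window, margins of 3 fixes, BIC selection;
  per-location σ²ₘ is the mean over all windows that scored the fix.
* **Evaluation** — shared reference grids, cell-based 50/95/99%
  isopleths with area/perimeter/complexity, AUC against presence cells
  (Mann–Whitney with half ties), Manly selection ratios w_i = u_i/a_i,
  seasonal splits, and a one-call `compare_estimators()`.
* **Synthetic telemetry** — a state-switching Brownian motion generator
  with shelter-site anchoring, a field-style fix schedule (4/day,
  reduced in the cold season), GPS error, and patchy categorical
  habitat rasters, so the whole pipeline is testable without any
  field data.

## Worked example

```r
library(rangebridge)

sim <- simulate_study_tracks(seed = 1)   # two synthetic animals, ~18-21 months
movement_summary(sim$track)
#>   animal_id n_fixes mean_step_m max_step_m total_path_m max_displacement_m
#> 1 SIM1         2400        211.      4017.      505849.              6363.
#> 2 SIM2         1896        117.      2113.      221536.              4394.

tr   <- dplyr::filter(sim$track, animal_id == "SIM1")
prof <- dbbmm_variance_profile(tr)       # window 11, margin 3
glance(prof)
#>   n_fixes window margin mean_sigma2m max_sigma2m
#> 1    2400     11      3       13003.     360261.

grid <- make_reference_grid(sim$track, cell_size = 25, buffer = 250)
ud   <- compute_bb_ud(tr, prof, grid)    # dBBMM utilization distribution
glance(isopleth_region(ud, 0.95))
#>   level n_cells  mass area_ha perimeter_m complexity
#> 1  0.95   46040 0.950   2878.       84500       29.4

home_range_auc(ud, tr)
#> [1] 0.9738
```

The movement summary says animal SIM1 took ~211 m steps on average with
bursts to 4 km; the variance profile spans nearly five orders of
magnitude (stopovers vs movement bouts); the 95% "activity area" is
about 2,878 ha; and the dBBMM UD ranks visited cells above unvisited
ones with AUC 0.974. `compare_estimators()` produces the same metrics
for all seven estimators on one shared grid, plus per-season areas and
habitat selection tables; `autoplot()` methods draw UDs, variance time
series and comparison charts, and `run_pipeline()` drives everything
from a YAML config (a thin CLI wrapper is installed under
`inst/scripts/rangebridge-pipeline.R`).

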