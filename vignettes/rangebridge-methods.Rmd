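---
title: "Methods: Brownian bridge home ranges and their evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Brownian bridge home ranges and their evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rangebridge)
```

## The model

A track is an ordered series of relocations $z_i = (x_i, y_i)$ at times
$t_i$, each with an isotropic per-axis location-error SD $\delta_i$
(metres), in a projected metric CRS. The package never transforms
coordinates: every formula below is Euclidean in metres, and results
are reported in metres and hectares.

**Brownian bridges.** Conditional on consecutive fixes, the animal's
position at fractional time $\alpha \in [0, 1]$ along the interval of
duration $T$ (hours) is bivariate normal with mean
$z_0 + \alpha (z_1 - z_0)$ and per-axis variance

$$ s(\alpha) = T \alpha (1 - \alpha)\, \sigma^2_m
   + (1 - \alpha)^2 \delta_0^2 + \alpha^2 \delta_1^2 . $$

$\sigma^2_m$ (m²/h) is the Brownian motion variance: the diffusion
rate that measures path irregularity. Hours were chosen as the time
base because field fix schedules are naturally expressed in hours;
every reported $\sigma^2_m$ in this package is in m²/h, and all
internal computations are unit-consistent.

**Estimating $\sigma^2_m$.** We leave out every second interior fix
(odd/even alternation, so no fix is both predictor and predictand) and
evaluate each left-out fix under the bridge spanned by its neighbours.
The per-axis variance of the left-out observation is the bridge
variance above *plus its own* $\delta_i^2$: the observation is the
bridge value plus independent GPS noise. Reference implementations
differ on whether the predicted fix's own error enters this variance;
we include it for generative consistency (our simulator adds
independent noise to the true position, and with that convention the
likelihood is exactly the generative density). Tracks with
$\delta = 0$ are unaffected by the choice. The negative log-likelihood
is minimized over $\log \sigma^2_m$ by golden-section search
(`stats::optimize`, tolerance $10^{-6}$ on the log scale) inside a
bracket defaulting to $[10^{-8},\; 10 \cdot \max(\text{step})^2 /
\min(\text{lag})]$; an optimum within $10^{-4}$ of either end (in
relative log-bracket units) is flagged as a boundary solution — this
happens, for instance, when interior fixes sit exactly on the
interpolation lines and the error terms absorb all apparent motion.

**The dynamic profile.** A window of 11 consecutive fixes (default)
slides along the track one fix at a time. Within a window, the
constant-variance model competes against single-breakpoint models: a
split after fix $j$ that leaves at least `margin` (default 3) fixes on
each side. Each part's variance is estimated on its own sub-track, so
no leave-one-out bridge straddles the candidate change; both models are
then scored by BIC *on the same full window term set* (each term under
the variance of the part holding its left-out fix, $k$ = number of
variance parameters, $n$ = number of leave-one-out terms). Scoring
different models on different term subsets would systematically favour
whichever model uses fewer terms, which in early development manifested
as spurious breakpoints on perfectly homogeneous tracks. Ties
(ΔBIC < $10^{-9}$) go to the no-breakpoint model. A candidate split is
feasible only if both parts contain at least 3 fixes *and* at least one
estimation term; consequently a window of 5 fixes with margin 2 has no
feasible breakpoint at all, and its profile provably equals the
single global estimate — a useful degenerate case for testing.

Every non-margin fix of a window records the winning model's variance
for its part; the final per-location $\sigma^2_m$ is the mean over all
windows that scored the fix (about `window − 2·margin` of them), the
track's unscored leading/trailing margins inherit the nearest scored
value, and per-interval variances are the means of their endpoint
values. At most one breakpoint is considered per window; multiple
behavioral shifts emerge across overlapping windows. The default
window of 11 fixes corresponds to roughly two days at four fixes/day
(conventionally quoted as 44 h, i.e. 11 × 4 h, though 11 fixes span 10
gaps ≈ 40 h; we record the conventional figure without adjudicating).

**From bridges to a UD.** Each interval's bridge density is averaged
over `n_alpha = 21` equally spaced α nodes with trapezoid weights,
weighted by the interval duration, summed over intervals, converted to
cell masses on the shared grid and renormalized to 1. Each node's
Gaussian is truncated beyond 4.5 SD (mass error < 1e−5 per node). A
constant profile reproduces the BBMM cell-for-cell; a varying profile
is the dBBMM. Intervals longer than an optional `max_lag_h` can be
excluded; the default bridges everything, including the longer
cold-season gaps, matching how such data are analysed in practice.

## The baseline estimators

**Percent MCP.** The `ceiling(n·p/100)` fixes closest to the arithmetic
mean centre (ties: earlier fix retained first) are kept and their
convex hull returned; area by the shoelace formula (1 ha = 10⁴ m²).
The ceiling never discards more than (100−p)% of fixes; the mean
centre with Euclidean ranking is the commonest MCP convention and is
deterministic.

**Fixed KDE.** Product-Gaussian kernels at every relocation, evaluated
at cell centres and renormalized. Bandwidth selectors:

* `href_bandwidth()`: $h = \sqrt{(\mathrm{var}_x + \mathrm{var}_y)/2}\,
  n^{-1/6}$, the standard ad hoc bivariate normal-reference rule,
  common to both axes.
* `lscv_bandwidth()`: minimizes the least-squares cross-validation
  criterion $\mathrm{CV}(h) = \int \hat f_h^2 - (2/n) \sum_i \hat
  f_{h,-i}(x_i)$ via its closed-form pairwise expression on a
  log-spaced grid of 100 points spanning $[0.05, 2] \times h_{ref}$. A
  minimizer at either grid end is reported as *non-convergence*: with
  many duplicated or tightly clustered fixes (an animal re-using
  shelter sites) CV(h) decreases without bound as $h \to 0$, the
  classic LSCV failure mode. Non-convergence is defined operationally
  (boundary minimizer) because no analytic criterion exists.
* `plugin_bandwidth()`: two-stage direct plug-in per axis via
  `KernSmooth::dpik` (Gaussian kernel, normal-reference start for the
  second-derivative functional). Per-axis bandwidths were chosen
  (rather than a common h) because that is the usual definition of the
  direct plug-in selector; reports flag the convention.
* `manual_bandwidth()`: a user-set common h, default 100 m — the usual
  "h₁₀₀" convenience; `match_bandwidth_to_area()` searches h so a KDE
  isopleth area matches a reference (e.g. dBBMM) area.

KDE kernels are evaluated exactly (full separable matrix products, no
truncation), so cell masses agree with a direct sum-over-points oracle
to ~1e−12 relative.

## Evaluation framework

All estimators for one comparison run on one shared reference grid
(default 25 m cells, 250 m buffer, origin snapped to the cell size),
because both AUC and areas are grid-dependent.

* **Isopleths** are cell sets: cells sorted by mass (ties: row, then
  column), included until the cumulative mass first reaches the level.
  They are minimal by construction and nested across levels. Perimeter
  is the rasterized boundary length (4-neighborhood, raster border
  counts); complexity = perimeter (m) / area (ha). Cell-set isopleths
  rather than smoothed vector contours keep the metrics deterministic
  and consistent with the pixel-based AUC; complexities should only be
  compared within this convention, since vector-GIS perimeters differ
  by a resolution-dependent factor.
* **AUC**: presence cells are cells containing ≥ 1 relocation (per-cell,
  not per-fix, so revisitation does not weight the score); absences are
  all other grid cells; the score is cell mass; AUC is the
  Mann–Whitney statistic with ties counted half. MCPs have no UD and
  are excluded; a non-converged LSCV is excluded and flagged.
* **Selection ratios**: used (50% isopleth) vs available (99%)
  habitat composition as cell-count proportions, $w_i = u_i / a_i$,
  with a habitat used but unavailable classified "undefined".
* **Seasons**: cold (Dec–Feb), dry (Mar–Jun), rainy (Jul–Nov) by
  default — named month ranges, even though they are unequal in length;
  an equal 4-month period splitter (`assign_periods()`) is provided as
  the alternative convention. Seasonal reruns refit $\sigma^2_m$ per
  season-contiguous block (a gap > 35 days starts a new block) rather
  than slicing the all-data profile, so windows never span the
  out-of-season gaps.

## The synthetic telemetry generator

Because the package must be testable end-to-end without any deposited
field data, `simulate_track()` generates tracks with exactly the
statistical structure the estimators assume: a discretized Markov chain
over behavioral states (switches only at fix times, exponential dwell),
given-state Gaussian increments with variance $\sigma^2_m \Delta t$ per
axis, optional shelter-site anchoring (entering the stationary state
snaps to the nearest site and holds), an observation schedule of four
daily fixes (06:30, 11:00, 16:00, 20:00) thinned to two in the cold
months, and independent Gaussian GPS error (default δ = 5.5 m, a
typical handheld-GPS accuracy). Switching only at fix times keeps the
true per-interval variance well-defined, which makes parameter-recovery
scoring exact.

The default two-animal study fixture (`simulate_study_tracks()`)
emulates a realistic VHF study of a large, shelter-using snake: 649 and
533 tracking days; stopover state (σ²ₘ = 2 m²/h, mean dwell 108 h)
anchored to 10 shelter sites spread over ~3.5 × 3.5 km; exploratory
state with σ²ₘ = 25,000 (adult-like) or 12,000 (juvenile-like) m²/h
and mean dwell 66 h, chosen so the mean step length lands at the
few-hundred-metre scale reported for such animals and roughly half the
fixes are sub-threshold stopover steps; and a three-fold slowdown of
state turnover in the cold months (`cold_activity_factor = 3`),
reflecting reduced winter activity — the same phenomenon that motivates
the reduced winter fix schedule.

What the generator deliberately does **not** emulate: attraction or
Ornstein–Uhlenbeck pull toward a range centre, terrain- or
habitat-driven movement, gradual (within-interval) behavior changes,
missed fixes, or anisotropic GPS error. Passing tests on this fixture
therefore demonstrate correct *estimation given the model*, not
robustness to the many ways real telemetry violates it.

Habitat rasters are threshold-of-smoothed-noise landscapes: white noise
smoothed by a separable Gaussian kernel at the requested patch scale,
cut at the quantiles of the target category fractions — fractions are
matched up to discretization and the map is autocorrelated at the
requested length scale, which is all the selection-ratio machinery
needs.

## Numerical choices and degenerate inputs

* UDs are renormalized to sum to exactly 1; isopleth logic refuses
  all-zero UDs; `ud_raster()` refuses negative cells.
* Bridge point masses ($s(\alpha) = 0$): density 0 away from the mean,
  `Inf` at it (documented sentinel); in UD integration the node's mass
  goes to the containing cell.
* MCP refuses < 3 non-collinear retained points; collinearity uses a
  scale-relative cross-product tolerance.
* LSCV/KDE refuse non-converged bandwidths unless overridden; the
  comparison pipeline builds the LSCV UD from the boundary bandwidth
  (flagged), mirroring field practice of still mapping the estimate.
* Grids must cover the data; points on the outer edge are clamped into
  the last cell.
* All simulation and analysis randomness is seeded explicitly;
  identical config + seed reproduce byte-identical pipeline artifacts.
* Raster interchange uses ESRI ASCII grids (.asc) with a CSV legend
  sidecar for categorical rasters — a plain-text, GIS-standard format;
  polygons are written as GeoJSON with traced cell-boundary rings
  (counter-clockwise exteriors, holes assigned by containment).

## Problem sizes used by the test suite

The suite exercises recovery at the scales where the asymptotics are
informative yet quick: constant-variance recovery on 1,001-fix hourly
tracks (20 replicates, median within 10% of truth), two-state
separation on ~1,100-fix tracks with a 10:1 variance ratio (20
replicates, median recovered ratio ≳ 7), and the full estimator
comparison on the ~2,400 + ~1,900-fix study fixture on a 25 m grid.
These sizes were chosen as the smallest at which the statistical
properties stabilize.

## Known limitations

* The windowed change-point estimator blurs behavior boundaries: the
  fix at a bout boundary can be assigned to either side (the two
  adjacent splits use different term subsets, so the BIC choice between
  them is noise-driven), and 1–2-fix excursions cannot be isolated by a
  single breakpoint per window. On the study fixture this leaves
  roughly 10–20% of stopover intervals with inflated variance, which
  spreads part of the core mass into a halo around shelter sites. With
  stopover mass sitting near one half of the UD — exactly where a
  50% isopleth cuts — the dBBMM core area is therefore sensitive to
  this contamination, and on pure Brownian fixtures it does not
  collapse onto the shelter cells as tightly as reported for real
  shelter-using snakes, where movement genuinely slows near shelters
  (structure the generator deliberately omits). The 95/99% activity
  areas, AUC rankings and variance time series are insensitive to it.
* AUC uses all non-presence grid cells as pseudo-absences, so its
  absolute value depends on the grid extent; only within-grid
  comparisons are meaningful.
* Complexity values are raster-convention-specific (see above).
* The analysis-ready variance table (`write_profile_csv()`) is exported
  for downstream mixed-model analysis of σ²ₘ against habitat, season
  and weather; fitting those models is out of scope here, and standard
  GLMM tooling applies directly.
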