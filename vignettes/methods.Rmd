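---
title: "Methods: disturbance mapping, agent attribution and fire hazard on synthetic landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disturbance mapping, agent attribution and fire hazard on synthetic landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firescape)
```

This vignette documents the models and procedures the package
implements, the assumptions behind them, the tunable parameters with
their defaults and rationale, what the synthetic-data generator does and
does not emulate, and the design choices made where the design was
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The analysis chain

The package reconstructs a complete desk workflow for mapping abrupt
forest damage and its consequences:

* a **damage map** from the difference of before/during annual index
  composites, classified per pixel, masked to pre-event forest, and
  cleaned of single-pixel noise;
* a **disturbance history** per pixel from annual NBR trajectories,
  segmented into piecewise-linear vertex fits whose declining segments
  (magnitude ≥ 0.1 NBR, duration 1–3 years) are the mapped losses,
  ranked into primary and secondary per pixel;
* **causal agents** (stand-replacing fire SRF, stand-replacing harvest
  SRH, non-stand-replacing NSR) classified per disturbance patch from
  spectral magnitudes, pre-disturbance NBR, duration, rate, patch area
  and the fractal shape index;
* an **elevated-fire-hazard** flag for damaged patches adjacent to
  fire-supporting land cover;
* design-based **area estimates** with standard errors, combined across
  the forest-mask and damage-model error sources and aggregated across
  regions;
* **fire-weather anomaly** detection and a per-index regression of
  burned area on seasonal fire weather.

Everything operates on co-registered single-grid rasters (`fs_grid`), a
deliberate simplification: reprojection and cross-sensor harmonisation
are out of scope.

## 2. Spectral model

Indices are consumed, not derived from radiance: `nbr()`, `ndvi()` and
`tct()` (the classical reflectance coefficient set, configurable) exist
for completeness and for ingesting band data, but the synthetic
generator emits index trajectories directly, because every downstream
stage consumes indices.

Composites are per-pixel medians over valid scenes; invalid (cloudy)
observations are `NA` and excluded pixel-wise. The delta composite is
`after − before` per layer; abrupt canopy loss appears as a strong
negative NBR/NDVI delta. Throughout the *patch feature* tables the
opposite ("drop") sign convention is used: `d_nbr`, `d_ndvi`, … are
positive for a decrease. Harvest *brightens* a site, so its Tasseled Cap
brightness drop is negative — this sign contrast, together with patch
shape, is what separates harvest from fire.

## 3. Trajectory segmentation

`fit_vertices()` finds, for every candidate segment count *k* up to
`max_segments`, the sum-of-squares-optimal set of vertex years among the
observations, by dynamic programming over observation knots. The series
are short (37 annual values), so the exact optimum is affordable; *k* is
then the largest count whose optimal fit still improves RMSE by at least
`rmse_improvement_tol`.

Two refinements in `fit_trajectory()` mirror the regression step of the
original temporal-segmentation algorithm this simplifies:

* **free-value refitting** — the final curve is a continuous
  piecewise-linear least-squares fit (vertex values are not forced
  through noisy observations), and each interior vertex may shift by one
  year where that lowers the residual sum of squares;
* **duration-aware densification** — a fitted declining segment of more
  than `max_duration` years and at least `min_delta` magnitude receives
  one additional SSE-optimal vertex, because a real 1–3-year loss easily
  absorbs one flat neighbouring year at the SSE optimum and would then
  be discarded by the duration rule.

The plain "insert a vertex at the largest residual" reading was
implemented first and rejected: a single insertion cannot capture a step
change (two vertices must move together), so it stalls precisely on
abrupt-disturbance trajectories, and it is not monotone in RMSE.

Defaults: `max_segments = 6` over 37 years, `rmse_improvement_tol =
0.01` NBR, despiking off (single-year full-recovery spikes can be damped
by a 3-point median filter, but the generator does not produce them).
Loss-segment semantics are fixed by the detection rules: magnitude ≥
`min_delta = 0.1` NBR, duration ∈ {1, 2, 3} years, rate =
magnitude/duration, `pre_nbr` = fitted NBR at the segment start. A
pixel's primary disturbance is its largest-magnitude segment (ties:
earlier start year, then larger rate). The reported disturbance year is
`start_year + 1`, the first declining observation, matching the
generator's event-year semantics. `year_assignment()` additionally
models the known late-season shift of annual detection: onsets after
day-of-year 232 (~20 August, configurable) are reported in the following
year.

Known limitations: recovery-rate and significance filters of the
original algorithm are omitted; events in the first two series years
lack a baseline and are unreliable, which is why the trajectory
simulator starts onsets at 1990.

## 4. Landscape metrics

A patch is a maximal connected set of same-class (or same-disturbance-
year) cells; connectivity defaults to 8 (queen), the convention of the
landscape-metrics literature, with 4 available everywhere. Perimeter is
exposed cell edges × resolution, with nodata and the grid boundary
counting as exposed — the standard raster perimeter, chosen because no
alternative definition was available. The fractal dimension index is

&nbsp;&nbsp;&nbsp;&nbsp;`FRAC = 2 ln(0.25 P) / ln(A)`,

P in meters, A in m²; any square patch gives exactly 1 and raster
patches lie in [1, 2). A single cell of 1 m² or less is rejected
(degenerate logarithm). Distances (`distance_to_class()`, hazard
adjacency) are exact Euclidean center-to-center distances via the
separable squared-distance transform; edge-to-edge distances would need
sub-pixel geometry that a 30 m raster cannot support. Majority
resampling takes the modal class per block, breaking ties toward the
smaller class code (deterministic); hexagonal summaries use flat-topped
regular hexagons anchored at the raster origin, assigning every cell
center to exactly one hexagon by cube-coordinate rounding, so hexagon
totals partition the mapped area exactly.

## 5. Classification

No external random-forest implementation is available in the target
environment, so `fs_forest_fit()` provides a seeded bagged-CART
ensemble: bootstrap resamples, a fresh random feature subset of size
`floor(sqrt(p))` at every node, Gini splits, majority vote. All
randomness flows through R's RNG, so a seed makes fitting and prediction
bit-reproducible. Default 500 trees; the pipeline uses 300 for speed at
its demo scale. The decision threshold for the binary damage model is a
0.5 vote share. The same contract serves the nine-class land-cover
model, the binary damage model and the three-class agent model.

Accuracy is reported as a confusion matrix with overall, user's
(commission) and producer's (omission) accuracies on a held-out set:
a disjoint labelled split for the damage model, a 20% stratified random
holdout per class for the agent model.

The NSR definition (delta-NBR < 0.25) is used to *generate and validate*
NSR exemplars only; the classifier itself is free to learn the boundary,
mirroring how such rules are used to assemble training data rather than
as hard classification rules.

## 6. Area estimation and uncertainty

`stratified_area_estimate()` implements the standard design-based
estimator: class proportion `p_k = Σ_i W_i · n_ik / n_i` over map strata
with weights `W_i`, variance `Σ_i W_i² p_ik (1 − p_ik) / (n_i − 1)`,
optionally with the finite-population correction (so a census yields the
exact area with zero SE). `combine_uncertainty()` multiplies the forest
proportion of the region by the damaged share of forest and, assuming
independent errors, adds relative variances (delta method); at a zero
point estimate it falls back to additive-scale propagation.

`aggregate_regions()` defaults to the **linear** sum of regional
uncertainty terms because the published multi-region total this package
mirrors is exactly the linear sum of its parts (4,715 + 1,925 + 1,274 =
7,914 alongside 24,180 + 7,293 + 7,116 = 38,589); root-sum-of-squares —
the conventional choice for independent errors — is available via
`method = "quadrature"`. The ± values are treated as standard errors;
the interval level was never named in the source material, which is a
documented interpretation, not a derivation.

## 7. Fire hazard

Land cover is reclassified into fire-supporting (cropland, grassland,
woodland, pre-event burned forest) and fire-inhibiting (bare soil,
built-up, water, wetland, and undamaged forest) classes; damaged cells
are the subject of the analysis and belong to neither set. Supporting
patches below 1 ha are discarded before any distance is measured. A
damaged patch is *elevated* when its minimum center-to-center distance
to a surviving supporting cell is at most `adjacency_distance_m`.

The adjacency cutoff defaults to 30 m — one cell at the 30 m analysis
resolution, the tightest defensible operationalisation of "adjacent"
since no explicit cutoff was stated — and is configurable. Proportions
are reported at the 0.09 ha (one 30 m cell) and 1 ha thresholds, both as
patch-count shares and as area shares, because published phrasings mix
the two readings. Raising the minimum supporting-patch area can only
remove neighbours (elevated proportion non-increasing); raising the
adjacency distance can only add them (non-decreasing) — both are tested
as properties.

## 8. Fire weather

Seasonal means cover 1 March–30 September inclusive. The window is 214
calendar days in every year — a leap year only shifts the day-of-year
bounds, since February 29 precedes March; a 215-day leap window is a
common miscount and is deliberately not reproduced. Leap handling
is data-driven — only a year actually containing day 366 shifts the
bounds — because synthetic series use a fixed 365-day calendar.

`zscore_series()` standardises a yearly series against its own mean and
sample SD, focal year included (no leave-one-out language existed to
justify excluding it); an all-constant series yields z = 0 everywhere.
Thresholds: 3 for disturbed-area series, 2 for fire-weather series —
seasonal weather means are far less dispersed, and with a ~37-year
series the maximum attainable z is about `(n−1)/√n ≈ 5.9`, so 3 is
already a strict bar. `regress_burned_area()` fits one-predictor OLS per
index (ISI and DC separately, untransformed); negative predictions are
floored at zero and flagged. No more model complexity is warranted for a
predictor that is expected to be weak; a log-area variant would be the
first extension if it were.

## 9. The synthetic world

`generate_scenario()` builds what the analysis assumes, and nothing
more:

* **Mosaic.** Nine land-cover classes with default proportions (forest
  0.35, cropland 0.25, grassland 0.12, woodland 0.08, wetland 0.05,
  water/built-up/bare-soil 0.04 each, pre-event burned forest 0.03),
  drawn by thresholding multi-scale smoothed Gaussian noise at the
  class-proportion quantiles — spatially coherent patches emulating a
  fragmented cropland–forest mosaic.
* **Events.** A schedule of (year, agent, count, size, severity,
  duration) rows. Harvests are exact-size rectangles (compact divisor
  pairs, placed by exhaustive summed-area-table search); fires and NSR
  events grow irregular footprints by seeded random accretion, so the
  fractal index contrast the agent model exploits is built in, not
  assumed. Severities respect the agent conventions (SRF/SRH ≥ 0.25
  delta-NBR, NSR < 0.25). Events are placed only where the current land
  cover *and* the contemporaneous 5-yearly forest mask are forest. Land
  cover evolves only at event footprints (burned forest for a decade
  after fire; bare soil then grassland after harvest; no change for
  NSR).
* **Trajectories.** Per-class spectral baselines, a linear ramp of the
  event severity over its duration (the event-year observation already
  shows the first step, as a leaf-on composite would), exponential
  recovery (e-folding 12 years for stand-replacing events, 4 for NSR),
  agent-specific multipliers onto NDVI and Tasseled Cap bands, i.i.d.
  Gaussian observation noise (default sd 0.02 NBR).
* **Weather.** Daily FWI/ISI/DC on a fixed 365-day calendar: a
  summer-peaked seasonal cycle plus between-year and daily noise;
  anomaly years receive an additive March–September shift of 2.5
  within-year SDs, guaranteeing the advertised "at least 2".
* **Reference samples.** Uniform or stratified-by-mapped-class sampling
  with mapped and true labels attached; empty strata contribute nothing
  and are reported.

`simulate_trajectories()` is the distilled single-event world used by
the segmentation acceptance study: flat baseline, one injected drop
(magnitude 0.2–0.7, onset 1990–2018), persistent post-disturbance level,
durations 60/30/10% for 1/2/3-year declines — most stand-replacing
losses express within one composite year, multi-year declines are the
minority. `simulate_agent_features()` draws patch features directly from
the designed agent contrasts at a chosen sample size.

What the generator does **not** emulate — and hence what a green test
does not establish: sensor and orbit effects (cloud gaps, SAR
backscatter, cross-sensor calibration), spatially correlated noise,
gradual multi-decade declines, mixed pixels at patch boundaries,
topography, and any fire-spread or radiative physics. Accuracies on this
world (the demo's damage model is near-perfect) are upper bounds, not
forecasts of real-data performance; the tests establish correctness of
the machinery, calibration of the uncertainty estimator, and the
qualitative structure of the results (the war-year pulse flags at z ≥ 3,
weather under-predicts it), not real-world skill.

## 10. Numerical and formatting choices

* Rasters are exchanged as ESRI ASCII grids, tables as CSV, configs and
  manifests as YAML — plain-text formats chosen because no GeoTIFF
  writer is available in the target environment; the `fs_grid` surface
  would take a GeoTIFF backend without interface changes.
* The distance transform encodes infinity as 10¹², far above any
  attainable squared pixel distance, keeping the lower-envelope
  arithmetic exact.
* Majority-resampling ties break toward the smaller class code;
  `rank_disturbances()` ties break toward the earlier start year, then
  the larger rate — all deterministic.
* Stage outputs are pure functions of (config, seed); the run manifest
  records per-file MD5 checksums, and re-running with the same seed
  reproduces them bit-for-bit (tested).
* Degenerate inputs have defined behaviour throughout: no damaged
  patches yields proportions reported as undefined rather than 0; a
  zero-variance yearly series yields z = 0 and no flags; an empty
  stratum warns and contributes its weight with zero observed
  proportion.
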