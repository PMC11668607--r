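---
title: "From LiDAR footprints to wall-to-wall forest biomass: methods and design"
author: "gediBiomass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From LiDAR footprints to wall-to-wall forest biomass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gediBiomass)
```

## The problem

Spaceborne full-waveform LiDAR of the GEDI type does not image the land
surface. It samples it: ~25 m footprints every 60 m along eight parallel
beam tracks 600 m apart, within a 4200 m swath, with repeated overpasses
crossing at different azimuths. Each footprint record carries canopy
metrics (cover, plant area index, foliage height diversity, gap
probability, waveform energy integrals, maximum height, ...) plus quality
fields. Two questions drive this package:

1. How well can footprint metrics be carried to a *continuous* surface by
   inverse-distance-weighted (IDW) interpolation, and how does that
   accuracy respond to footprint density?
2. How well can plot-level aboveground biomass (AGB, t/hm²) be estimated
   from the interpolated surfaces with machine-learning regressors
   trained on allometric plot biomass?

Everything runs on synthetic scenes whose geometry and statistical
structure emulate the real acquisition, so the full workflow is testable
without any satellite download; the same functions accept real L2B
granules (`readL2B()`) or CSV tables.

## The models

**Allometry.** Single-tree biomass follows binary power laws in DBH
$D$ (cm) and height $H$ (m), per-tree mass in kg:

$$M_{spruce} = 0.09152\,D^{2.21060}H^{0.25663},\qquad
  M_{fir} = 0.06127\,D^{2.05753}H^{0.50839}.$$

Plot density is the tree-mass sum converted to tonnes divided by plot
area in hm². The per-tree unit (kg) follows the forestry-standard
convention; it is stated prominently because plot-level magnitudes
depend on it.

**IDW.** The prediction at $x_0$ is
$Z^*(x_0)=\sum_i \lambda_i Z(x_i)$ with
$\lambda_i = d_{i0}^{-p}/\sum_j d_{j0}^{-p}$ over the $N$ nearest
measured points. Defaults: $p = 2$, $N = 12$, unlimited search radius,
30 m cells — the source method states none of these, so conventional
geostatistical defaults are used and all are exposed in
`idwParams()`/`idwRasterize()`. Numerical conventions, fixed and tested:

* a query within $10^{-9}$ m of a measured point returns that
  measurement (exact interpolator; no division by zero);
* ties at the $N$-th neighbour distance break on the lower shot id, so
  predictions are deterministic;
* weights sum to one, hence predictions stay inside the convex hull of
  neighbour values;
* grids are axis-aligned, row-major, origin at the *upper-left* corner,
  predictions at cell centres; nodata cells are tagged in the ASCII-grid
  writer.

The engine (an Rcpp loop) is cross-checked in the test suite against an
independent brute-force R implementation to $10^{-10}$ relative.

**Accuracy metrics.** $R^2 = 1-\sum(\hat y_i-y_i)^2/\sum(y_i-\bar y)^2$,
$RMSE = \sqrt{\frac1n\sum(\hat y_i-y_i)^2}$,
$MAE = \frac1n\sum|\hat y_i-y_i|$. With constant observations the $R^2$
denominator vanishes; `evalMetrics()` flags this (`r2_defined = FALSE`)
instead of propagating NaN. Nodata predictions are excluded and counted.

**Density experiment.** `runDensityExperiment()` thins the filtered
shots to every $k$-th per beam line ($k \in \{10,30,50,70,100\}$ by
default), splits 70/30 into interpolation and validation shots, and
evaluates each variable at the held-out locations. Validation shots are
never interpolation sources. Whether accuracy rises or falls with
density depends on the sampling geometry (track-clustered validation
points sit close to their own track's training points), so the runner
reports the trend but the package asserts no direction — only the
mechanics (completeness, determinism, the counting law of thinning).

**Estimators.** Random forest (300 trees, `mtry` 2), radial-basis
support vector regression (C = 1, $\gamma$ = 0.92 — the `g` of the
e1071 convention), and k-nearest-neighbour regression (k = 9), under
seeded plot-level 10-fold cross-validation. Fold metrics, their mean,
and metrics pooled over all out-of-fold predictions are all reported;
the fold split is simple random without spatial blocking, which is
flagged as a limitation for spatially autocorrelated plots. Features
enter as the raster cell containing the plot centre (no resampling,
matching IDW surface semantics); nearest-footprint attachment was
considered and rejected as the default because surfaces are the
product under study. Variable screening ranks Pearson correlations with
plot AGB (significance marks at 0.05/0.01) and selects the top 5 by
absolute value; zero-variance features are flagged and ranked last.

## The synthetic scene

`simulateScene()` fixes the study conditions; its defaults are the
conditions under which the package's end-to-end guarantees are stated.

* **Extent and tracks:** 20 km x 20 km planar scene; 50 overpasses with
  azimuths spread over 0-180 degrees and seeded perpendicular swath
  offsets, eight beams each — about 140k raw shots whose overlap
  produces the characteristic footprint lattice. Planar metres
  throughout; no geodesy in synthetic mode.
* **Metric fields:** Gaussian random fields with exponential covariance
  (sill per metric, range 3000 m, nugget fraction 0.05), simulated by
  circulant embedding (negative embedding eigenvalues clamped — the
  standard remedy, negligible here). The correlation range is set at
  the scale of landscape canopy gradients in montane terrain; the true
  spatial covariance of real footprint metrics is unknown, so these are
  acknowledged stand-ins. Canopy-structure metrics share a latent
  canopy-density field (loadings in `defaultFieldParams()`), because
  cover, PAI, FHD, gap probability and the energy integrals are
  strongly cross-correlated in real forests — independent fields would
  misrepresent both the screening step and the estimator's task.
  Proportion metrics are clamped to [0, 1].
* **Quality contamination:** independent per criterion — 5% of shots
  get `quality_flag` 0, 2% get `degrade_flag` 1, 5% get sensitivity
  redrawn below 0.9. Real flag correlations are out of scope. After
  the standard filter (quality 1, degrade 0, sensitivity >= 0.9) about
  124k shots remain; interval-100 thinning leaves ~1.2k.
* **Plots:** 138 plots of 0.0667 hm² (the common inventory plot size),
  uniform over the scene. A latent AGB target of mean 100 and SD
  45 t/hm² is coupled to the five structure metrics (cover, FHD, PAI
  positively; gap probability and ground energy negatively) with noise
  equal to 30% of the AGB SD; tree lists (lognormal DBH, Chapman-
  Richards height curve with 10% multiplicative noise, 60% spruce) are
  grown until the allometric plot biomass reaches the target. Plot AGB
  is therefore *always* the allometry module applied to the same tree
  list; the one-tree overshoot is the discretisation error visible in
  coupling tests.
* **Waveforms:** Gaussian noise floor plus rectangular signal segments,
  with the injected extent recorded as ground truth. The smoothing
  "width of 6.5 ns" is interpreted as the Gaussian sigma (configurable
  to FWHM), converted to bins via the bin width, with reflective
  boundary padding. Signal bounds detection is implemented literally
  as printed: search range = first/last super-threshold bin,
  toploc/botloc = outermost positions with two adjacent
  super-threshold bins; smoothing widens a detected extent by roughly
  $1.3\sigma$ per side at 50x contrast, which the detection tests
  account for. Second-pass peak filtering and ground-peak
  identification are out of scope (L2B products already contain those
  results).

What the scene does *not* emulate — radiometry, orbital mechanics,
cloud cover, geolocation error, correlated quality flags, non-target
species — bounds what passing tests show: they validate the method
chain, not any real-world accuracy claim.

## Reproducible problem sizes

The test suite exercises two scales, chosen as the package's own test
conditions: a 6 km "tiny" scene (8 overpasses, 120 m field grids, 40
plots) for unit tests, and the full default scene for the end-to-end
recovery check, which runs five seeds of: simulate, filter, thin at
interval 100, rasterise all 14 metrics at 60 m, screen, and
cross-validate the random forest. Under these conditions the mean
pooled out-of-fold R² across seeds is above 0.5 and a permuted-response
null stays below 0.1; both are asserted in the acceptance tests, and
nothing stronger is claimed.

## Degenerate inputs and edge rules

* zero-sill fields are constant at the mean; zero overpasses give an
  empty footprint table; empty tree lists give zero plot AGB;
* `thinFootprints(interval = 1)` is the identity; per-beam thinning is
  the default, pooled available via `perBeam = FALSE` (the source is
  ambiguous; rank-based is deterministic, and a seeded random-offset
  mode reproduces "random selection every k shots");
* filtering is idempotent and order-preserving, with per-criterion
  removal counts in the report;
* points on a grid's east/south edge belong to the last cell;
* an isolated single super-threshold bin yields a search range but no
  toploc/botloc (two adjacent bins are required by definition).

## Known limitations

IDW is the only interpolator (no kriging or anisotropy, by design);
cross-validation folds are not spatially blocked; the latent-field
cross-correlation is a single-factor approximation; HDF5 reading
delegates to the `h5py` Python library rather than an in-process
binding; GeoTIFF output is not provided — rasters are written as ESRI
ASCII grids, footprints as CSV/GeoJSON.
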