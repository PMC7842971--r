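---
title: "Imputing forest structure wall-to-wall: methods and design notes"
author: "forstruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing forest structure wall-to-wall: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forstruct)
```

## The problem

Airborne laser scanning (ALS) and digital aerial photogrammetry deliver
detailed gridded forest structural attributes — canopy height percentiles,
canopy cover — but only over the patches that were flown. Optical satellite
archives (Landsat-class sensors) cover everything, every year, but observe
reflectance, not structure. `forstruct` transfers structure from the flown
cells (*references*) to the unflown cells (*targets*) by k-nearest-neighbour
imputation: each target receives the response values of the reference cells
it most resembles in predictor space. The predictors are temporal summaries
of spectral index series plus terrain variables, so both the current state
and the multi-decadal trajectory of each pixel inform the match.

## The model

### Predictors from image time series

For each annual composite we compute spectral indices (NDVI, NBR, Tasseled
Cap brightness/greenness/wetness; `calc_indices()`), then reduce each
pixel's annual index trajectory to three summary metrics
(`temporal_summary()`):

* **median** — the typical state over the record;
* **IQR** (Q75 − Q25, linear-interpolation quantiles) — variability;
* **Theil–Sen slope** — the median of all pairwise slopes
  $(y_j - y_i)/(t_j - t_i)$, a trend estimator robust to outlier years.

Theil–Sen uses calendar years, not layer indices, so a series with missing
years still yields slopes in units per year. Pixels with fewer than
`min_valid` finite years (default 3) are NoData: a slope from two points is
a single pairwise ratio with no median smoothing, which we consider too
fragile to map. The quantile method (type 7, linear interpolation) is the
common default and is fixed so that IQR maps are reproducible across
machines.

### Structure-guided sampling

Reference cells are abundant (every flown cell) but spatially autocorrelated
and structurally biased toward whatever the acquisition happened to cover.
`kmeans_stratify()` clusters the *response* space — each response band
standardized to zero mean and unit variance so metres and percent weigh
equally — and `draw_sample()` draws per-stratum quotas proportional to
stratum area (largest-remainder apportionment, so quotas sum exactly to *n*
and are within one point of exact proportionality). A minimum pairwise
distance between sampled cell centroids (Euclidean, map units) thins the
sample against spatial autocorrelation. Enforcement is greedy over a seeded
random candidate order with a bounded number of attempts; when a quota is
unreachable under the distance constraint the sampler returns fewer points
and warns rather than silently relaxing the constraint.

We use `stats::kmeans` with Lloyd's algorithm and 10 seeded random restarts.
Strata are relabelled by ascending first-band cluster mean so labels are
stable across runs with the same seed.

`partition()` assigns folds within each stratum: points are shuffled
(seeded), every fold receives an equal base share, and remainders go one
each to the currently smallest folds. Per-stratum and total fold sizes both
differ by at most one, so each held-out fold spans the full structural range
— 230 points in 5 folds always give 46 held out and 184 trained on.

### Random-forest proximity k-NN

One regression forest is grown per response variable (via `ranger`), with
`ntree` trees and `mtry` split candidates. The nearness of target $t$ to
reference $r$ is the proportion of trees — pooled over all per-response
forests — in which $t$ and $r$ fall in the same terminal node. Pooling makes
the proximity a single supervised nearness measure informed by every
response at once, which is what lets $k = 1$ impute all responses
simultaneously from the same reference, preserving among-attribute
allometry. With $k > 1$ targets receive the simple or proximity-weighted
mean of their k nearest references (weighted is the default: it preserves
the information in the proximities). Plain Euclidean (on standardized
predictors) and Mahalanobis distances are available as alternative nearness
measures; the covariance for Mahalanobis can be computed on raw or
standardized predictors (`mahalanobis_on`).

Determinism: proximity ties are broken by lowest reference ID, every forest
is seeded, and `ranger` runs single-threaded, so maps are bit-reproducible.

`predict_targets()` processes the predictor raster in chunks of
`chunk_rows` rows; at most one chunk's terminal-node matrix and one
`chunk × n_ref` proximity block are held at a time, and the output is
bit-identical for any chunk size and for tile-then-mosaic execution.

### Accuracy and importance

`accuracy()` computes, over held-out pairs,

$$R^2 = 1 - \frac{SSR}{SST}, \qquad
RMSE = \sqrt{\tfrac{1}{n}\sum_i(\hat y_i - y_i)^2}, \qquad
bias = \tfrac{1}{n}\sum_i(\hat y_i - y_i),$$

with relative forms as percentages of the observed mean. $R^2$ may be
negative; $RMSE \ge |bias|$ always. `var_imp()` reports each predictor's
out-of-bag permutation importance (MSE increase when the predictor is
permuted, computed at fit time under the model seed), z-scored across
predictors within each response — negative scaled importance means below
the average predictor — plus the mean scaled importance across responses.

## Raster data model and preprocessing

The package carries its own raster currency: a `grid_raster` is a
rows × cols × bands array on a north-up `grid_spec` (origin, cell sizes,
CRS tag), with NoData as `NA` throughout and cell-center semantics for all
point operations. On-disk formats are plain text: single-band ESRI ASCII
grids and a JSON-headed multi-file stack; `grid_spec` serializes to JSON.
No reprojection engine is bundled, so `match_resolution()` resamples
(bilinear for continuous layers, nearest for categorical — the caller must
say which) within a single CRS and errors on CRS mismatch. Bilinear weights
renormalize over the finite part of the 2×2 support, so isolated NoData
cells do not bleed outward.

`focal_multiband()` defaults to NoData propagation (any missing window
member voids the cell) because smoothing across data gaps silently mixes
populations; `ignore` is opt-in. `edges()` buffers NoData by Chebyshev
(queen) distance — square buffers compose with square focal windows — and a
flag (default off) optionally treats the raster boundary as NoData. Whether
boundary cells should be buffered is genuinely ambiguous in field practice,
hence a flag rather than a hard-coded guess.

## The synthetic scene

`make_scene()` generates the full input stack on one grid with a known
generating process, so every stage is testable without downloads:

* latent fields (vegetation density, trend, soil brightness, elevation) are
  seeded white noise smoothed by a separable Gaussian kernel
  (`corr_length` cells) — spatially autocorrelated, which is precisely what
  the minimum-distance sampler exists to defeat;
* yearly six-band reflectance is linear in the (clamped) vegetation
  trajectory plus noise, so a noiseless band series has an exactly
  recoverable Theil–Sen slope;
* each response is a probability-integral-transformed affine combination
  (with a small interaction) of the vegetation and elevation fields, scaled
  to realistic ranges (height percentile 2–42 m, cover 5–90 %). The PIT
  makes the driver uniform, so responses spread evenly across their range —
  a forest with a full structural gradient — and vegetation dominates, so
  spectral medians and the DEM should lead the importance ranking;
* response noise is Gaussian with sd equal to `response_noise_frac`
  (default 10 %) of the noiseless response range.

Defaults describe a 150 × 150 grid of 20 m cells (3 km × 3 km) with a
25-year annual series — large enough for a 230-point sample at 75 m spacing,
small enough that the full pipeline runs in a couple of minutes on one CPU.
What the scene does *not* emulate: radiometric artifacts (clouds, haze,
compositing gaps), disturbance events (abrupt trajectories), non-Gaussian
response noise, and registration error between layers. Passing tests
therefore demonstrate the correctness of the machinery and its behavior
under the stated generating process, not performance on real imagery.

### The recovery benchmark

The end-to-end benchmark imputes with $k = 5$ and proximity weighting
rather than the $k = 1$ of a typical production run. The reason is what the
benchmark measures: with $k = 1$ a held-out prediction copies one noisy
reference, so its error contains two independent noise draws and mostly
reflects the injected noise, not the model's ability to recover the link.
Averaging five neighbours suppresses the copied-noise term and isolates
link recovery, which is the property under test. Under the default noise
(10 % of range) the attainable held-out $R^2$ is about 0.89 for a perfect
model; the pipeline reaches ≈ 0.81–0.88 across seeds with bias within
±1 %. The $k = 1$ configuration (200 trees, `mtry` 3) is exercised
separately for its closure property: every imputed vector is an exact
reference row with a matching ID.

## Worked example

```{r example, eval = FALSE}
sc <- make_scene(scene_params(seed = 1))
bm <- band_map(blue = 1, green = 2, red = 3, nir = 4, swir1 = 5, swir2 = 6)

idx <- raster_time_series(
  lapply(sc$ts$layers, calc_indices,
         indices = c("NDVI", "TCB", "TCG", "TCW"), bands = bm),
  sc$ts$years)
tm <- temporal_summary(idx)                       # 12 metric bands
preds <- grid_raster(
  array(c(tm$values, sc$dem$values, sc$slope$values),
        c(150, 150, n_bands(tm) + 2)),
  tm$spec, c(tm$band_names, "DEM", "DEM_slope"))  # 14 predictors

km  <- kmeans_stratify(sc$responses, 5, seed = 1)
pts <- draw_sample(km$strata, sample_design(230, 5, min_dist = 75, seed = 1))
pts <- get_sample_values(sc$responses, pts)
pts <- get_sample_values(preds, pts)

fl <- partition(pts$stratum, "kfold", kfold = 5, seed = 1)
m  <- train_nn(pts[preds$band_names], pts[c("p95", "cover")],
               k = 1, folds = fl, ntree = 200, mtry = 3, seed = 1)
accuracy_report(m$cv)
map <- predict_targets(m, preds, chunk_rows = 64)
```

The same sequence is available declaratively through `run_pipeline()` and
the thin command-line wrapper in `inst/cli/forstruct.R`.

## Known limitations

* No reprojection: all layers must share a CRS before entering the package.
* The stack I/O format is package-specific plain text, not GeoTIFF;
  interchange with GIS software goes through single-band ESRI ASCII grids.
* Regression forests are always grown on continuous responses; categorical
  response variables are not supported.
* The minimum-distance sampler is greedy, not optimal: for very tight
  spacings it may return a shortfall where a cleverer packing exists (it
  warns when it does).
* Importance z-scores are undefined for a single predictor or equal raw
  importances; both degenerate to 0 with a warning.
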