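---
title: "Modelling urban sound-type prevalence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling urban sound-type prevalence: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement model

The pipeline assumes an intermittent audio monitoring campaign: recorders
at fixed (long-term) and rotating (week-long) sites capture a 10 s clip
every 10 minutes — 144 clips per full site-day — and a classifier returns
up to three sound classes per clip. Fine classes are grouped into seven
categories (road transport, animal/insect, music, speech, aircraft,
geophysical nature, other) by a total mapping: unknown labels fall into
*other*, so a labelled clip always maps somewhere. Categories are not
mutually exclusive; a clip can evidence up to three categories at once.

**Prevalence** — the percentage of clips in a (site, date, period) cell in
which a category was detected — is the dependent variable. Day is
06:00–21:59 (96 scheduled clips), night 22:00–05:59 (48 clips). Two
conventions needed a decision the source material leaves open:

* *Night attachment.* A night spans midnight. We attach it to the date on
  which it begins (22:00 of day *d* through 05:59 of *d*+1 is "night of
  *d*"), keeping each night contiguous.
* *Training rows.* Model rows are site-**date**-period prevalences, not
  per-site period means. The 30-day fixed-site subsampling only makes
  sense on dated rows; per-site averaging is deferred to
  prediction-summary time. This follows the reading that dated prevalences
  "for each date of monitoring" feed the model while "average prevalence
  at each location" describes reporting.
* *Partial days.* First/last deployment days produce partial cells; cells
  with fewer than half the scheduled clips for their period are dropped
  (configurable via `min_clip_fraction`), since a prevalence from a
  handful of clips is mostly binomial noise.

Fixed sites record for months; rotating sites for 7 days. To use the
fixed sites' temporal coverage without letting a handful of locations
dominate, each fixed site is subsampled to 30 random distinct dates
(`subsample_fixed_site_days`, seeded).

## Spatial predictors

Buffer statistics at 50/100/200/500 m radii around each target (site or
grid-cell center): total road length by class (major, secondary/tertiary,
minor, all), counts of eight POI kinds, building count, waterway length,
mean NDVI, mean population density, and land-cover composition shares;
plus unbuffered elevation and distance to the nearest major road. The
inventory is data (`default_predictor_specs()`), not code, so it can be
edited without touching the pipeline.

Numerical conventions, chosen so tests can use exact oracles:

* All geometry is planar Euclidean in meters — no geographic lat/lon math.
* Buffers are **closed** disks (distance ≤ radius), avoiding measure-zero
  ambiguity at the boundary.
* Raster statistics use the **cell-center-in-disk** rule rather than
  area-weighted partial cells: deterministic, fast, and with 50 m cells
  against ≥50 m radii the difference is small. The brute-force test
  oracles enumerate cell centers under the same rule.
* Empty count/length buffers are a real absence and yield 0; an empty
  raster-mean disk is structural (radius smaller than the cell pitch at
  the domain edge) and is an error/flag, never a silent 0.
* Elevation enters as the point value at the target (the buffer statistic
  for elevation is not specified anywhere; a point value is the simplest
  defensible choice and is configurable in the spec table).

## The random forest LUR

One regression forest per category × period: 500 trees, `mtry = p/3`,
minimum node size 5, fitted on the selected buffer columns. Because no
random-forest package is guaranteed in the execution environment, the
estimator is implemented in the package (Rcpp): bootstrap resampling,
CART splits minimizing SSE over a random feature subset per node, in-bag
bookkeeping for out-of-bag (OOB) prediction. It draws from R's RNG, so
`set.seed()` makes forests bit-reproducible. Forest predictions are
averages of training-response leaf means, hence always within
`[min(y), max(y)]` — predictions need no post-hoc clamping to [0, 100],
and tests assert rather than code this.

**Buffer-radius selection.** One forest is fitted on *all* candidate
(variable, radius) columns simultaneously; permutation importance (mean
increase in OOB MAE over `n_perm = 10` seeded permutations) is computed
per column; for each multi-radius variable the radius with the largest
importance is retained, ties broken toward the smaller (more local)
radius. Fitting one joint forest rather than refitting per radius lets
the radii compete directly and costs one fit. The number of permutations
and the perturbed accuracy metric are deliberate defaults (the method's
description leaves both open); both are spec parameters.

**A-priori exclusions.** Predictors judged not sound-producing in a
period are excluded from that period's candidate set before selection —
concretely, schools are day-only; all other defaults apply to both
periods.

**Validation.** Site-grouped 10-fold cross-validation: sites are
partitioned into 10 disjoint folds (~10% of sites each, seeded), and all
rows of a held-out site leave the training set together, so the metric
measures prediction at genuinely unmonitored locations. We read the
"10-fold / 10% of sites held out 10 times" phrasing as disjoint
partition — under disjointness the two phrasings coincide. Buffer
selection is performed once on the full table and held fixed across
folds; re-selecting inside each fold would also be defensible but is not
what a select-then-validate workflow does. Reported: median absolute
error and mean absolute error (deviation), mean error (bias), Pearson r,
per fold and pooled.

**Residual diagnostics.** Per-site mean OOB residuals are tested for
spatial autocorrelation with Moran's I, using row-standardized
inverse-distance weights with no cutoff by default (k-nearest and
distance-band schemes available); the analytic expectation is −1/(n−1)
and inference uses the normality-assumption variance. Across models of a
period, absolute residuals are min-max scaled to [0, 1] per model and
summed per site (`combined_residual_score`), flagging sites that are
poorly predicted by many sound types at once; a model with constant
absolute residuals has zero range and contributes 0 with a warning.

**Unreliable models.** A model whose training response is more than 80%
zeros cannot generalize above 0% prevalence; it is fitted and archived
but flagged `reliable = FALSE` and its surfaces are not written by the
pipeline. In the default synthetic world this is the geophysical-nature
category, whose prevalence is rare and heavily zero-skewed — the same
failure mode that makes spatially-driven models inappropriate for
temporally-driven sounds like rain and wind.

## Prediction surfaces and masking

Predictions are made at 50 m grid-cell centers using the identical
feature specs as the sites, guaranteeing train/predict schema identity.
Cells where monitoring sites are unrepresentative are masked, with
accumulating reasons: `no_roads` (no road polyline intersects the cell
square — "contains roads" is operationalized as polyline-intersects-cell,
with a buffer-distance alternative available), `water` (cell fully
water), `natural_only` (all land cover in the cell is the natural "other"
class *and* no road). A cell crossed by any road is never masked. Zonal
summaries (median, quartiles, min, max over unmasked cells) are reported
for the whole area, the core zone, and road-proximity classes
(nearest-road class within 100 m, a threshold the source material does
not state).

## The SoundType Index

Level surfaces (L_day, L_night, dBA) and prevalence surfaces live on
different scales. Levels are min-max normalized over unmasked cells —
**per period**, since day and night level distributions differ and the
composite metrics are built per period — and prevalences become
proportions in [0, 1]. The composite is the weighted geometric mean
`norm_level^w1 * proportion^w2` with equal weights (0.5, 0.5) by default;
the weighted-geometric form is adopted as the standard meaning of
"geometric aggregation with equal weighting", and alternative weights are
exposed. Two consequences are documented rather than patched:

* a cell at the exact level minimum gets index 0 regardless of
  prevalence (geometric annihilation);
* min-max parameters are city-specific, so they are stored with every
  output surface — without them the index cannot be compared across
  cities.

## The synthetic city: what it emulates, and what a green test means

`simulate_city()` generates the complete stated world: covariate rasters
with an urban→peri-urban gradient (core: low NDVI ≈ 0.08, high population
density ≈ 35,000/km²; periphery: NDVI ≈ 0.3, density ≈ 1,700/km² — chosen
to match the descriptive statistics of a rapidly urbanizing coastal
city), a four-class land cover sampled from gradient-dependent weights, a
river corridor, roads in three classes (arterials through the core,
connectors, and minor streets dense enough that most built cells lie on a
street, as in a real urban fabric), eight POI kinds concentrated in
commercial land cover, and buildings proportional to population.

The campaign defaults are the real design scaled to desk size: 9 fixed +
120 rotating sites, stratified random sampling over the four land-use
classes with 50% of rotating sites oversampled into the core zone (the
central square covering 25% of the area), 7-day rotating deployments,
270-day fixed deployments (middle of the reported 227–322 range),
subsampled to 30 days for modelling. The study area is 3 × 3 km at 50 m
cells rather than 1,500 km² — the full extent is computationally
pointless at desk scale and adds nothing statistically; this is stated
wherever results are reported.

The sound process is per-category independent Bernoulli per clip, with
logistic probability in three standardized local covariates (NDVI, log
population density, major-road proximity `exp(-d/300 m)`) plus a
day/night intercept offset. Coefficients were chosen once to reproduce
the qualitative structure reported for a real campaign — road transport
dominant and road-driven, animal/insect sounds opposite in sign to road
transport on road proximity and higher at night, music and speech
population-driven with speech collapsing at night, geophysical nature
rare and zero-skewed (~0.2% median), aircraft and other flat — and are
not revisited. When more than three categories fire in a clip, the three
with the largest sampled prominence draws are kept, mimicking a top-3
classifier and reproducing the information loss a real pipeline has.
Levels are `base + gain·exp(-d_major/τ) + noise` (base 55 dBA, gain 14,
τ 250 m, σ 1.5) with one shared noise field per cell and a fixed 7 dBA
night offset, so `L_day − L_night = 7` exactly and levels decay
monotonically from major roads.

What this world does **not** emulate: temporal weather structure (rain
comes as i.i.d. rare presence, not storm events), classifier error
(detections are draws from the truth, so prevalence is unbiased — the
separate `validate_classifier()` module handles accuracy/PPV/NPV against
manual labels), traffic volume, sound propagation physics, or correlated
category occurrence beyond what shared covariates induce. A green
parameter-recovery test therefore establishes that the pipeline recovers
a logistic-in-covariates spatial signal through the full
prevalence→features→forest→surface chain — not that it would achieve any
particular accuracy on a real city.

Closed-form expected prevalences (`expected_prevalence()`) make the
generator falsifiable: held-out predictions are correlated against
`100·logistic(β₀ + β·z(site))` directly, and empirical clip presence is
checked against binomial confidence bounds.

## Reproducibility

One global seed derives per-stage seeds deterministically; all randomness
(raster noise, sampling, bootstrap, permutations, folds) flows from R's
RNG. `run_all()` writes a manifest with per-stage wall time and md5 of
every output file; re-running with the same config and seed reproduces
every file byte for byte (wall times are not outputs and are excluded
from determinism comparisons). Rasters are serialized as ESRI ASCII
grids and vectors as GeoJSON — text formats chosen because no binary
geospatial writer is assumed in the environment; coordinates are planar
meters without a CRS tag.

## Known limitations

* The forest cannot extrapolate beyond the training-response range; in
  sparsely monitored strata the surfaces compress toward the observed
  range.
* Permutation importance on correlated radii of the same variable splits
  importance between them; selection still picks the argmax, but the
  margin shrinks as radii correlate (the recovery test quantifies this on
  a single-radius signal).
* Moran's I uses the normality-assumption variance, not randomization
  inference; its type-I calibration is checked empirically in the tests.
* The CLI and pipeline serialize forests to JSON without in-bag records;
  permutation importance requires the in-memory fit.
* No traffic-flow/volume predictors, no hourly models, no
  L_den-style 24 h penalty metric, and no uncertainty surfaces — all out
  of scope by design.
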