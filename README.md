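# soundlur

Random forest land use regression (LUR) for urban **sound-type prevalence**,
with a composite **SoundType Index** combining sound levels and sound-type
presence.

Most noise epidemiology reduces the acoustic environment to a single
A-weighted level. But a city's soundscape is a mixture of road traffic,
human speech, music, animal and insect sounds, and geophysical nature
sounds, each with different health relevance. This package implements a
city-scale pipeline for characterizing that mixture from intermittent audio
monitoring: low-cost recorders capture a 10 s clip every 10 minutes at a
network of fixed (year-long) and rotating (week-long) monitoring sites; a
classifier reports up to three sound classes per clip; and the analysis
turns those detections into city-wide, 50 m resolution exposure surfaces.
It is aimed at exposure scientists and environmental epidemiologists who
want source-resolved sound surfaces for health studies, and at urban sound
planners.

## The method

For each site *s*, date *d* and period *p* (day 06:00–21:59, night
22:00–05:59), the **prevalence** of sound category *c* is

```
prev(s, d, p, c) = 100 * (# clips in which c was detected) / (# clips)
```

Prevalences are regressed on buffer-based spatial predictors — road length
by class, counts of points of human activity, mean NDVI, mean population
density, land-cover composition (all at 50/100/200/500 m radii), elevation,
and distance to the nearest major road — using regression random forests
(500 trees, mtry = p/3). One model is fitted per category × period (10
models; aircraft and "other" are excluded a priori, and a model whose
training response is >80 % zeros is flagged unreliable and not reported).
The best buffer radius per predictor is chosen by permutation importance
(mean increase in out-of-bag MAE over seeded permutations), predictors not
sound-producing in a period are excluded a priori (e.g. schools at night),
and accuracy is assessed by site-grouped 10-fold cross-validation (all rows
of a held-out site leave together), reporting MdAE, MAE, ME and Pearson r,
with Moran's I tests for residual spatial autocorrelation.

Predictions are made on a 50 m grid, masked where the monitoring network is
not representative (cells with no roads, fully water, or fully natural land
cover). Finally, the per-cell **SoundType Index** in [0, 1] aggregates the
min-max-normalized level surface L (dBA) with the presence proportion:

```
index = normalized(L)^0.5 * (prev/100)^0.5      (equal-weight geometric mean)
```

Because no clip-level measurement campaign is publicly available, the
package ships a first-class synthetic-city generator (`simulate_city()`)
that emulates the covariate rasters, road/POI vector layers, the stratified
monitoring campaign (50 % of rotating sites oversampled into the urban
core) and a logistic ground-truth sound process, so every stage is testable
end to end and parameter recovery can be verified against closed-form
expectations.

## Worked example

```r
library(soundlur)
cfg <- read_pipeline_config(system.file("extdata", "demo_config.yaml",
                                        package = "soundlur"))
res <- run_all(cfg, out_dir = "soundlur_demo")
print(res$cv[["road_transport_day"]])
#> <cv_report> road_transport / day: pooled MdAE 4.09, MAE 5.80, ME -0.01, r 0.900 (n=192)

summarize_surface(res$surfaces[["road_transport_day"]],
                  surface_zones(res$features$grid, cfg$city,
                                res$city$vectors))
#>                      zone n_cells  min   q1 median   q3  max
#> 1              whole_area     534 41.3 60.4   74.4 86.1 95.9
#> 2                    core     170 58.9 76.4   91.3 94.6 95.9
#> 3              near_major      65 73.7 83.5   86.3 93.4 95.9
#> 4 near_secondary_tertiary     133 45.7 68.8   77.4 84.5 95.7
#> 5              near_minor     336 41.3 57.0   67.1 84.5 95.8
```

Reading this: daytime road-transport sounds are predicted present ~74 % of
the time across the unmasked demo city, rising to ~91 % in the urban core
and ~86 % within 100 m of major roads — the monotone road-proximity
gradient the land-use-regression model is built to capture. Held-out-site
cross-validation (sites never seen in training) explains the prediction
error: median absolute error ~4 percentage points, negligible bias, r =
0.90 against observed prevalences. `run_all()` writes every artifact
(rasters as ESRI ASCII grids, vectors as GeoJSON, tables as CSV, fitted
forests as JSON, and a manifest with per-stage seeds and md5 hashes) under
`out_dir`; re-running with the same config and seed reproduces the files
byte for byte.

A command-line interface mirrors the stages:

```sh
./exec/soundlur run-all --config inst/extdata/demo_config.yaml --seed 5
./exec/soundlur simulate --config cfg.yaml --out-dir out
./exec/soundlur prevalence --clips out/clips.csv --sites out/sites.csv --out-dir out
```

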