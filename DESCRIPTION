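Package: soundlur
Title: Random Forest Land Use Regression for Urban Sound-Type Prevalence
Version: 0.1.0
Authors@R:
    person("Soundscape", "Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: City-scale analysis of urban sound environments from
    intermittent audio-clip classifications. Computes sound-type prevalence
    per site, date and day/night period; extracts circular-buffer spatial
    predictors (road length, points of interest, NDVI, population density,
    land-cover composition) at monitoring sites and prediction-grid cells;
    fits seeded 500-tree random forest land use regression models with
    permutation-based buffer-radius selection, site-grouped cross-validation
    and Moran's I residual diagnostics; produces masked 50 m prediction
    surfaces; and derives a composite SoundType Index by equal-weight
    geometric aggregation of min-max normalized sound levels with sound-type
    presence proportions. Includes a synthetic-city generator that emulates
    the covariate rasters, vector layers, stratified monitoring campaign and
    logistic ground-truth sound process the analysis assumes, so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
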