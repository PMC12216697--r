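# Shared fixtures, built in code and cached for the duration of the run.
# The "small" city keeps module tests fast; the "default" city (the full
# stated world: 9 fixed + 120 rotating sites) is only built by the
# acceptance tests that need it.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

small_config <- function(seed = 42) {
  city_config(extent_m = c(1500, 1500), n_rotating_sites = 24,
              n_fixed_sites = 2, campaign_days_fixed = 12, seed = seed)
}

small_city <- function() cached("small_city", function() {
  simulate_city(small_config())
})

small_artifacts <- function() cached("small_artifacts", function() {
  city <- small_city()
  prev <- compute_prevalence(city$clips)
  tab <- subsample_fixed_site_days(model_table(prev, city$sites),
                                   30, seed = 7)
  layers <- list(rasters = city$rasters, vectors = city$vectors)
  fm <- build_feature_matrix(city$sites, layers)
  list(city = city, prev = prev, table = tab, layers = layers,
       features = fm)
})

default_city <- function() cached("default_city", function() {
  simulate_city(city_config(seed = 202))
})

default_artifacts <- function() cached("default_artifacts", function() {
  city <- default_city()
  prev <- compute_prevalence(city$clips)
  tab <- subsample_fixed_site_days(model_table(prev, city$sites),
                                   30, seed = 11)
  layers <- list(rasters = city$rasters, vectors = city$vectors)
  fm <- build_feature_matrix(city$sites, layers)
  list(city = city, prev = prev, table = tab, layers = layers,
       features = fm)
})

# minimal ground-truth object with spatially constant covariate fields,
# for closed-form and Monte-Carlo checks
const_gt <- function(coefs,
                     night_offset = setNames(rep(0, nrow(coefs)),
                                             rownames(coefs)),
                     fields = c(ndvi = 0, pop = 0, road = 0),
                     cell = 50, n = 30) {
  f <- function(v) sgrid(matrix(v, n, n), cell = cell)
  structure(list(
    coefs = coefs, night_offset = night_offset,
    fields = list(ndvi = f(fields["ndvi"]), pop = f(fields["pop"]),
                  road = f(fields["road"])),
    level_model = list(base_dba = 55, gain_dba = 14, tau_m = 250,
                       night_offset_dba = 7, noise_sd_dba = 1.5)),
    class = "ground_truth")
}

gt_coef_row <- function(category, intercept, ndvi = 0, pop = 0, road = 0) {
  m <- matrix(c(intercept, ndvi, pop, road), nrow = 1,
              dimnames = list(category,
                              c("intercept", "ndvi", "pop", "road")))
  m
}
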