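test_that("city_config validates its invariants", {
  expect_error(city_config(extent_m = c(1230, 1500)), "divisible")
  expect_error(city_config(core_fraction = 1.2), "core_fraction")
  expect_error(city_config(strata_weights = c(a = 1)), "strata_weights")
  cfg <- city_config()
  expect_s3_class(cfg, "city_config")
  expect_equal(sum(cfg$strata_weights), 1)
})

test_that("covariate rasters are deterministic, registered and bounded", {
  cfg <- small_config(seed = 7)
  r1 <- generate_covariate_rasters(cfg)
  r2 <- generate_covariate_rasters(cfg)
  expect_identical(r1$ndvi$values, r2$ndvi$values)
  expect_identical(r1$land_cover$values, r2$land_cover$values)

  expect_true(all(r1$ndvi$values >= -1 & r1$ndvi$values <= 1))
  expect_true(all(r1$pop_density$values >= 0))
  dims <- lapply(r1[c("ndvi", "pop_density", "land_cover", "elevation",
                      "water")], function(g) dim(g$values))
  expect_length(unique(dims), 1)
  expect_setequal(unique(as.vector(r1$land_cover$values)), 1:4)
})

test_that("urban gradient: core is less green and denser than periphery", {
  city <- small_city()
  g <- city$rasters$ndvi
  ctr <- grid_centers(g)
  core <- in_core_zone(ctr[, 1], ctr[, 2], city$config)
  expect_lt(mean(g$values[matrix(core, nrow(g$values))]),
            mean(g$values[matrix(!core, nrow(g$values))]))
  pop <- city$rasters$pop_density$values
  expect_gt(mean(pop[matrix(core, nrow(pop))]),
            mean(pop[matrix(!core, nrow(pop))]))
})

test_that("vector layers cover all road classes and stay in the extent", {
  city <- small_city()
  classes <- vapply(city$vectors$roads, `[[`, "", "class")
  expect_setequal(unique(classes),
                  c("major", "secondary_tertiary", "minor"))
  ext <- city$config$extent_m
  for (f in city$vectors$roads) {
    expect_true(all(f$coords[, 1] >= 0 & f$coords[, 1] <= ext[1]))
    expect_true(all(f$coords[, 2] >= 0 & f$coords[, 2] <= ext[2]))
  }
  expect_true(all(city$vectors$pois$x >= 0 & city$vectors$pois$x <= ext[1]))
  expect_true(all(city$vectors$pois$y >= 0 & city$vectors$pois$y <= ext[2]))
})

test_that("POIs concentrate in cbi land cover relative to 'other'", {
  city <- small_city()
  lc <- city$rasters$land_cover
  poi_class <- lc$levels[grid_value_at(lc, city$vectors$pois$x,
                                       city$vectors$pois$y)]
  n_cells <- table(factor(lc$levels[lc$values], levels = lc$levels))
  dens <- table(factor(poi_class, levels = lc$levels)) / as.numeric(n_cells)
  expect_gt(dens[["cbi"]], dens[["other"]])
})

test_that("site sampling honors counts, core fraction and strata", {
  cfg <- city_config(n_rotating_sites = 120, n_fixed_sites = 9,
                     core_fraction = 0.5, seed = 5)
  rasters <- generate_covariate_rasters(cfg)
  sites <- sample_sites(cfg, rasters)
  expect_equal(nrow(sites), 129)
  expect_equal(sum(sites$site_type == "rotating"), 120)
  rot <- sites[sites$site_type == "rotating", ]
  # half the rotating sites oversampled into the core, +/- 1 site
  expect_lte(abs(sum(rot$in_core) - 60), 1)
  expect_setequal(unique(rot$stratum), landcover_classes())
  expect_false(any(duplicated(sites$site_id)))

  # determinism and the n_fixed = 0 edge
  expect_identical(sample_sites(cfg, rasters), sites)
  cfg0 <- city_config(n_fixed_sites = 0, n_rotating_sites = 8, seed = 5)
  r0 <- generate_covariate_rasters(cfg0)
  expect_true(all(sample_sites(cfg0, r0)$site_type == "rotating"))
})

test_that("clip schedule: 96 day and 48 night clips per full site-day", {
  city <- small_city()
  sid <- city$sites$site_id[city$sites$site_type == "fixed"][1]
  clips <- city$clips[city$clips$site_id == sid, ]
  one_day <- clips[as.Date(clips$timestamp) ==
                     city$config$campaign_start + 1, ]
  expect_equal(nrow(one_day), 144)
  periods <- assign_period(one_day$timestamp)
  expect_equal(sum(periods == "day"), 96)
  expect_equal(sum(periods == "night"), 48)
})

test_that("clip presence follows the logistic ground truth", {
  # p = 0.7 via logit, one category, ~10k clips at one site
  gt <- const_gt(gt_coef_row("road_transport", qlogis(0.7)))
  cfg <- city_config(extent_m = c(1500, 1500), n_fixed_sites = 1,
                     n_rotating_sites = 0, campaign_days_fixed = 70,
                     seed = 9)
  site <- data.frame(site_id = "F001", x = 750, y = 750,
                     site_type = "fixed", stratum = "cbi", in_core = TRUE)
  clips <- simulate_clip_labels(site, gt, cfg)
  n <- nrow(clips)
  expect_equal(n, 70 * 144)
  phat <- mean(!is.na(clips$class1))
  expect_lt(abs(phat - 0.7), 3 * sqrt(0.7 * 0.3 / n))

  # p = 0 never fires
  gt0 <- const_gt(gt_coef_row("road_transport", -Inf))
  clips0 <- simulate_clip_labels(site, gt0, cfg)
  expect_true(all(is.na(clips0$class1)))

  # empty site list -> empty output
  expect_equal(nrow(simulate_clip_labels(site[0, ], gt, cfg)), 0)
})

test_that("at most 3 classes per clip, even when many categories fire", {
  cats <- c("road_transport", "animal_insect", "music", "speech", "other")
  coefs <- do.call(rbind, lapply(cats, function(cc)
    gt_coef_row(cc, qlogis(0.9))))
  gt <- const_gt(coefs)
  cfg <- city_config(extent_m = c(1500, 1500), n_fixed_sites = 1,
                     n_rotating_sites = 0, campaign_days_fixed = 2,
                     seed = 13)
  site <- data.frame(site_id = "F001", x = 750, y = 750,
                     site_type = "fixed", stratum = "cbi", in_core = TRUE)
  clips <- simulate_clip_labels(site, gt, cfg)
  n_classes <- rowSums(!is.na(cbind(clips$class1, clips$class2,
                                    clips$class3)))
  expect_true(all(n_classes <= 3))
  expect_gt(mean(n_classes == 3), 0.5)  # 5 cats at p=.9: usually truncated
})

test_that("expected_prevalence matches the closed form", {
  # logistic(0) at a zero-covariate site
  gt <- const_gt(gt_coef_row("speech", 0))
  site <- data.frame(x = 100, y = 100)
  expect_equal(expected_prevalence(gt, site, "speech", "day"), 50)
  # intercept 1, single coefficient 2 on a covariate at 0.5:
  # 100 / (1 + exp(-2)) = 88.07971
  gt2 <- const_gt(gt_coef_row("speech", 1, ndvi = 2),
                  fields = c(ndvi = 0.5, pop = 0, road = 0))
  expect_equal(expected_prevalence(gt2, site, "speech", "day"),
               88.0797077977882, tolerance = 1e-10)
  # extreme intercept saturates at 0
  gt3 <- const_gt(gt_coef_row("speech", -1e6))
  expect_equal(expected_prevalence(gt3, site, "speech", "day"), 0)
  # night offset shifts the linear predictor
  gt4 <- const_gt(gt_coef_row("speech", 0),
                  night_offset = c(speech = qlogis(0.8)))
  expect_equal(expected_prevalence(gt4, site, "speech", "night"), 80)
})

test_that("level surfaces decay from major roads with a fixed night offset", {
  city <- small_city()
  lv <- city$levels
  expect_true(all(is.finite(lv$L_day$values)))
  expect_equal(lv$L_day$values - lv$L_night$values,
               matrix(7, nrow(lv$L_day$values), ncol(lv$L_day$values)))
  d <- cpp_min_dist_to_segments(grid_centers(lv$L_day),
                                road_segments(city$vectors, "major"))
  on_road <- which.min(d)
  far <- which(d >= 600)  # exp(-600/250): >12 dBA below on-road, past noise
  expect_gt(lv$L_day$values[on_road], max(lv$L_day$values[far]))
  # seeded determinism
  lv2 <- simulate_level_surface(city$rasters, city$vectors,
                                city$ground_truth, city$config)
  expect_identical(lv$L_day$values, lv2$L_day$values)
})

test_that("raster round-trips through ESRI ASCII preserve values", {
  city <- small_city()
  path <- withr::local_tempfile(fileext = ".asc")
  write_asc(city$rasters$ndvi, path)
  back <- read_asc(path)
  expect_equal(back$values, city$rasters$ndvi$values, tolerance = 1e-12)
  expect_equal(back$cell, 50)
})
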