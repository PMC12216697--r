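test_that("line length in buffer: exact cases and sampling oracle", {
  seg <- matrix(c(0, 0, 1000, 0), 1)
  expect_equal(line_length_in_buffer(seg, c(0, 0), 500), 500)
  expect_equal(line_length_in_buffer(seg, c(5000, 5000), 500), 0)
  expect_error(line_length_in_buffer(seg, c(0, 0), -10), "positive")

  set.seed(31)
  for (i in 1:100) {
    segs <- matrix(runif(8, -800, 800), 2, 4)
    center <- runif(2, -200, 200)
    r <- sample(c(50, 100, 200, 500), 1)
    got <- line_length_in_buffer(segs, center, r)
    want <- oracle_line_length(segs, center, r)
    expect_lt(abs(got - want), max(0.005 * max(want, 1), 0.5))
  }
})

test_that("point count in buffer: closed-disk boundary and brute force", {
  pts <- data.frame(x = c(499.9, 500.1), y = c(0, 0))
  expect_equal(point_count_in_buffer(pts, c(0, 0), 500), 1L)
  expect_equal(point_count_in_buffer(data.frame(x = 3, y = 4),
                                     c(3, 4), 50), 1L)
  expect_equal(point_count_in_buffer(data.frame(x = 0, y = 500),
                                     c(0, 0), 500), 1L)  # boundary counts
  set.seed(5)
  pts <- data.frame(x = runif(1000, 0, 2000), y = runif(1000, 0, 2000))
  for (r in c(50, 100, 200, 500)) {
    center <- runif(2, 0, 2000)
    want <- sum((pts$x - center[1])^2 + (pts$y - center[2])^2 <= r^2)
    expect_equal(point_count_in_buffer(pts, center, r), want)
  }
})

test_that("raster mean in buffer matches enumeration oracle", {
  g_const <- sgrid(matrix(0.2, 20, 20), cell = 50)
  expect_equal(raster_mean_in_buffer(g_const, c(500, 500), 200), 0.2)
  # r smaller than half a cell centered on a cell center -> that cell
  g <- sgrid(matrix(seq_len(400), 20, 20), cell = 50)
  expect_equal(raster_mean_in_buffer(g, c(25, 25), 20), g$values[1, 1])
  # checkerboard vs exhaustive enumeration
  cb <- sgrid(outer(1:20, 1:20, function(i, j) (i + j) %% 2), cell = 50)
  set.seed(8)
  for (i in 1:20) {
    center <- runif(2, 100, 900)
    expect_equal(raster_mean_in_buffer(cb, center, 500),
                 oracle_raster_mean(cb, center, 500))
  }
  expect_warning(raster_mean_in_buffer(g, c(-5000, -5000), 50), "no raster")
})

test_that("land-cover composition shares sum to 1 and match enumeration", {
  lc <- sgrid(matrix(3L, 20, 20), cell = 50, levels = landcover_classes())
  sh <- landcover_composition_in_buffer(lc, c(500, 500), 200)
  expect_equal(unname(sh["cbi"]), 1.0)
  expect_equal(sum(sh), 1.0)
  # vertical half/half stripe through the disk center
  half <- matrix(1L, 20, 20); half[, 11:20] <- 4L
  lc2 <- sgrid(half, cell = 50, levels = landcover_classes())
  sh2 <- landcover_composition_in_buffer(lc2, c(500, 500), 300)
  ctr <- grid_centers(lc2)
  inside <- (ctr[, 1] - 500)^2 + (ctr[, 2] - 500)^2 <= 300^2
  want_formal <- mean(as.vector(lc2$values)[inside] == 1L)
  expect_equal(unname(sh2["formal_residential"]), want_formal)
  expect_equal(sum(sh2), 1.0, tolerance = 1e-9)
})

test_that("distance to nearest major road: exact and densified oracle", {
  road <- matrix(c(-1000, 0, 1000, 0), 1)
  expect_equal(distance_to_nearest_major_road(c(0, 100), road), 100)
  expect_equal(distance_to_nearest_major_road(c(250, 0), road), 0)
  expect_error(
    distance_to_nearest_major_road(c(0, 0), matrix(numeric(0), ncol = 4)),
    "major")
  set.seed(17)
  for (i in 1:20) {
    segs <- matrix(runif(8, 0, 1500), 2, 4)
    center <- runif(2, 0, 1500)
    got <- distance_to_nearest_major_road(center, segs)
    expect_lt(abs(got - oracle_distance(segs, center)), 0.5)
  }
})

test_that("feature matrix: schema, composition and empty-buffer zeros", {
  a <- small_artifacts()
  fm <- a$features
  specs <- attr(fm, "specs")
  n_cols <- sum(vapply(seq_len(nrow(specs)), function(i)
    length(soundlur:::spec_columns(specs[i, ])), 0L))
  expect_equal(ncol(fm), 1 + n_cols)
  expect_false(anyNA(fm))

  # compositional consistency: matrix values equal per-op calls
  site <- a$city$sites[3, ]
  segs <- road_segments(a$city$vectors, "major")
  expect_equal(fm[3, "road_major@200"],
               line_length_in_buffer(segs, c(site$x, site$y), 200))
  expect_equal(fm[3, "ndvi@100"],
               raster_mean_in_buffer(a$city$rasters$ndvi,
                                     c(site$x, site$y), 100))
  expect_equal(fm[3, "dist_major_road"],
               distance_to_nearest_major_road(c(site$x, site$y),
                                              a$city$vectors))
  sch <- point_count_in_buffer(
    a$city$vectors$pois[a$city$vectors$pois$kind == "school", ],
    c(site$x, site$y), 500)
  expect_equal(fm[3, "poi_school@500"], sch)

  # missing layer errors by name
  bad <- specs[1, ]; bad$source <- "tramways"
  expect_error(build_feature_matrix(a$city$sites, a$layers, bad),
               "tramways")
})

test_that("features are monotone in radius and translation invariant", {
  a <- small_artifacts()
  fm <- a$features
  for (v in c("road_all", "poi_church", "building")) {
    cols <- paste0(v, "@", c(50, 100, 200, 500))
    m <- as.matrix(fm[, cols])
    expect_true(all(diff(t(m)) >= 0))  # nested disks: non-decreasing
  }
  # translation invariance of the geometry primitives
  segs <- road_segments(a$city$vectors, "major")
  shift <- c(1234, -987)
  segs_s <- segs + matrix(shift, nrow(segs), 4, byrow = TRUE)[, c(1, 2, 1, 2)]
  center <- c(700, 700)
  expect_equal(line_length_in_buffer(segs, center, 200),
               line_length_in_buffer(segs_s, center + shift, 200))
  expect_equal(distance_to_nearest_major_road(center, segs),
               distance_to_nearest_major_road(center + shift, segs_s))
})

test_that("site features equal grid features at coincident cell centers", {
  a <- small_artifacts()
  grid <- build_grid(a$city$config$extent_m, 50)
  cellpick <- grid[c(100, 200), ]
  fake_sites <- data.frame(site_id = c("A", "B"), x = cellpick$x,
                           y = cellpick$y)
  fm_site <- build_feature_matrix(fake_sites, a$layers)
  fm_grid <- build_feature_matrix(cellpick, a$layers)
  expect_equal(as.numeric(fm_site[1, -1]), as.numeric(fm_grid[1, -1]))
  expect_equal(as.numeric(fm_site[2, -1]), as.numeric(fm_grid[2, -1]))
})

test_that("feature matrix round-trips through CSV with its sidecar", {
  a <- small_artifacts()
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(a$features, path)
  back <- read_feature_matrix(path)
  expect_equal(names(back), names(a$features))
  expect_equal(as.matrix(back[, -1]),
               as.matrix(as.data.frame(a$features)[, -1]),
               tolerance = 1e-12)
})
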