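#' Synthetic-city configuration
#'
#' Describes the synthetic study area and monitoring campaign used to
#' exercise the full prevalence -> LUR -> surface -> index pipeline without
#' external data. Defaults emulate, at desk scale, a campaign with 9
#' year-long fixed sites and 120 week-long rotating sites selected by
#' stratified random sampling over four land-use classes, with 50% of
#' rotating sites oversampled into the urban core.
#'
#' @param extent_m width and height of the study area in meters; must be
#'   divisible by `cell_size_m`.
#' @param cell_size_m raster and prediction-grid resolution (m).
#' @param n_fixed_sites,n_rotating_sites numbers of fixed (long-term) and
#'   rotating (week-long) monitoring sites.
#' @param core_fraction fraction of rotating sites placed inside the core
#'   zone (the central square covering 25% of the area).
#' @param strata_weights named allocation weights over the four land-use
#'   strata for rotating sites.
#' @param campaign_days_fixed,campaign_days_rotating deployment lengths in
#'   full days.
#' @param campaign_start first deployment date (`Date` or string).
#' @param seed integer seed; a fixed seed makes every generated artifact
#'   reproducible.
#' @return A validated list of class `city_config`.
#' @export
city_config <- function(extent_m = c(3000, 3000),
                        cell_size_m = 50,
                        n_fixed_sites = 9,
                        n_rotating_sites = 120,
                        core_fraction = 0.5,
                        strata_weights = c(formal_residential = 0.25,
                                           informal_residential = 0.25,
                                           cbi = 0.25,
                                           other = 0.25),
                        campaign_days_fixed = 270,
                        campaign_days_rotating = 7,
                        campaign_start = "2019-04-10",
                        seed = 1L) {
  extent_m <- as.numeric(extent_m)
  if (length(extent_m) == 1) extent_m <- rep(extent_m, 2)
  if (any(extent_m %% cell_size_m != 0))
    stop("configuration error: extent_m must be divisible by cell_size_m")
  if (core_fraction < 0 || core_fraction > 1)
    stop("configuration error: core_fraction must be in [0, 1]")
  if (is.null(names(strata_weights)) ||
      !setequal(names(strata_weights), landcover_classes()))
    stop("strata_weights must be named with the four land-use classes")
  if (any(strata_weights < 0) || sum(strata_weights) <= 0)
    stop("strata_weights must be non-negative and not all zero")
  structure(list(
    extent_m = extent_m, cell_size_m = cell_size_m,
    n_fixed_sites = as.integer(n_fixed_sites),
    n_rotating_sites = as.integer(n_rotating_sites),
    core_fraction = core_fraction,
    strata_weights = strata_weights / sum(strata_weights),
    campaign_days_fixed = as.integer(campaign_days_fixed),
    campaign_days_rotating = as.integer(campaign_days_rotating),
    campaign_start = as.Date(campaign_start),
    seed = as.integer(seed)), class = "city_config")
}

#' Land-use classes of the synthetic land-cover raster
#'
#' Four classes mirroring a typical rapidly-urbanizing city land-cover map:
#' formal (medium/low-density) residential, informal (high-density)
#' residential, commercial/business/industrial (cbi), and "other"
#' (parks, forest, grassland, water, barren land).
#'
#' @return Character vector of class names.
#' @export
landcover_classes <- function() {
  c("formal_residential", "informal_residential", "cbi", "other")
}

# deterministic per-stage seed derived from one global seed (< 2^31)
derive_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 101 + 7 * stage) %% 2147483647L)
}

# core zone: central square with half the side length (25% of the area)
in_core_zone <- function(x, y, config) {
  w <- config$extent_m[1]; h <- config$extent_m[2]
  abs(x - w / 2) <= w / 4 & abs(y - h / 2) <= h / 4
}

# separable moving-average blur with edge replication (window 2k + 1);
# used to give white-noise fields some spatial coherence
box_blur <- function(m, k) {
  blur_vec <- function(v) {
    n <- length(v)
    vp <- c(rep(v[1], k), v, rep(v[n], k))
    cs <- c(0, cumsum(vp))
    (cs[(2 * k + 1) + seq_len(n)] - cs[seq_len(n)]) / (2 * k + 1)
  }
  m <- apply(m, 2, blur_vec)
  t(apply(m, 1, blur_vec))
}

smooth_noise <- function(nr, nc, k = 3) {
  z <- box_blur(matrix(rnorm(nr * nc), nr, nc), k)
  z / max(sd(z), 1e-12)  # unit-variance coherent field
}

#' Generate the synthetic covariate rasters
#'
#' Builds registered grids with a configured urban-to-peri-urban gradient:
#' the core has low NDVI and high population density, the periphery the
#' reverse, matching the spatial structure a land-use-regression analysis
#' assumes. Land cover is drawn per cell from gradient-dependent class
#' weights; a river corridor is carved out as water (class "other").
#'
#' @param config a [city_config()].
#' @return List of class `covariate_rasters` with [sgrid] layers `ndvi`
#'   (unitless, clamped to `[-1, 1]`), `pop_density` (people/km^2, > 0),
#'   `land_cover` (integer-coded, see [landcover_classes()]), `elevation`
#'   (m) and `water` (0/1 fully-water flag).
#' @export
generate_covariate_rasters <- function(config) {
  stopifnot(inherits(config, "city_config"))
  set.seed(derive_seed(config$seed, 1))
  w <- config$extent_m[1]; h <- config$extent_m[2]; cell <- config$cell_size_m
  nc <- w %/% cell; nr <- h %/% cell
  xs <- (seq_len(nc) - 0.5) * cell
  ys <- ( seq_len(nr) - 0.5) * cell
  X <- matrix(rep(xs, each = nr), nr, nc)
  Y <- matrix(rep(ys, times = nc), nr, nc)
  # normalized distance from the city center, in [0, 1]
  g <- sqrt((X - w / 2)^2 + (Y - h / 2)^2) / sqrt((w / 2)^2 + (h / 2)^2)

  ndvi <- pmin(pmax(0.08 + 0.22 * g + 0.05 * smooth_noise(nr, nc), -1), 1)
  log_pop <- log(35000) - 3.0 * g + 0.35 * smooth_noise(nr, nc)
  pop <- exp(log_pop)
  elev <- 20 + 40 * (X / w) + 4 * smooth_noise(nr, nc, k = 5)

  # land cover: gradient-dependent class weights, sampled per cell
  eps <- 0.35 * smooth_noise(nr, nc)
  gg <- pmin(pmax(g + 0.08 * eps, 0), 1)
  w_cbi <- exp(-(gg / 0.28)^2)
  w_inf <- exp(-((gg - 0.30) / 0.22)^2)
  w_for <- exp(-((gg - 0.58) / 0.22)^2)
  w_oth <- 0.05 + 1.6 * gg^2
  wsum <- w_cbi + w_inf + w_for + w_oth
  u <- matrix(runif(nr * nc), nr, nc)
  p1 <- w_for / wsum; p2 <- p1 + w_inf / wsum; p3 <- p2 + w_cbi / wsum
  lc <- 4L - (u < p3) - (u < p2) - (u < p1)  # codes 1..4 follow class order
  storage.mode(lc) <- "integer"

  # river corridor: sinuous north-south band near the eastern third
  river_x <- 0.70 * w + 0.04 * w * sin(ys / h * 2 * pi)
  water <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) water[i, abs(xs - river_x[i]) <= 55] <- 1L
  lc[water == 1L] <- 4L  # water is part of the "other" class

  out <- list(
    ndvi = sgrid(ndvi, cell = cell),
    pop_density = sgrid(pop, cell = cell),
    land_cover = sgrid(lc, cell = cell, levels = landcover_classes()),
    elevation = sgrid(elev, cell = cell),
    water = sgrid(water, cell = cell),
    config = config)
  class(out) <- "covariate_rasters"
  out
}

# largest-remainder rounding of weights * n to integers summing to n
allocate_counts <- function(weights, n) {
  raw <- weights / sum(weights) * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    take <- order(raw - k, decreasing = TRUE)[seq_len(rem)]
    k[take] <- k[take] + 1
  }
  as.integer(k)
}

#' Generate the synthetic vector layers
#'
#' Roads in three classes (major arterials crossing the city, secondary and
#' tertiary connectors, short minor streets in built-up areas), points of
#' interest of eight kinds concentrated in commercial/business land cover,
#' a waterway centerline, and building points proportional to population
#' density.
#'
#' @param config a [city_config()].
#' @param rasters output of [generate_covariate_rasters()].
#' @return List of class `vector_layers` with `roads` (list of features,
#'   each `list(id, class, coords)`), `pois` (data.frame `x, y, kind`),
#'   `waterways` (list of polyline features) and `buildings` (data.frame
#'   `x, y`).
#' @export
generate_vector_layers <- function(config, rasters) {
  stopifnot(inherits(config, "city_config"),
            inherits(rasters, "covariate_rasters"))
  set.seed(derive_seed(config$seed, 2))
  w <- config$extent_m[1]; h <- config$extent_m[2]

  jitter_line <- function(from, to, n_vertex = 12, amp = 40) {
    t <- seq(0, 1, length.out = n_vertex)
    base <- cbind(from[1] + t * (to[1] - from[1]),
                  from[2] + t * (to[2] - from[2]))
    perp <- c(-(to[2] - from[2]), to[1] - from[1])
    perp <- perp / sqrt(sum(perp^2))
    off <- amp * sin(t * pi) * rnorm(1) + amp / 3 * rnorm(n_vertex) * sin(t * pi)
    coords <- base + outer(off, perp)
    coords[, 1] <- pmin(pmax(coords[, 1], 0), w)
    coords[, 2] <- pmin(pmax(coords[, 2], 0), h)
    coords
  }

  roads <- list()
  add_road <- function(class, coords) {
    roads[[length(roads) + 1]] <<- list(
      id = sprintf("%s_%02d", class, length(roads) + 1),
      class = class, coords = coords)
  }
  # major: two crossing arterials plus a diagonal
  add_road("major", jitter_line(c(0, h * 0.5), c(w, h * 0.5)))
  add_road("major", jitter_line(c(w * 0.5, 0), c(w * 0.5, h)))
  add_road("major", jitter_line(c(0, 0), c(w * 0.85, h)))
  # secondary/tertiary: connectors between random edge points via interior
  for (i in 1:10) {
    from <- c(runif(1, 0, w), sample(c(0, h), 1))
    if (runif(1) < 0.5) from <- rev(from)
    to <- c(w, h) / 2 + runif(2, -w / 4, w / 4)
    add_road("secondary_tertiary", jitter_line(from, to, n_vertex = 8))
  }
  # minor: short streets seeded in built-up cells, dense enough that most
  # built cells lie on or near a street (as in a real urban fabric)
  built <- which(rasters$land_cover$values != 4L &
                   rasters$water$values == 0L, arr.ind = TRUE)
  n_minor <- min(max(40, nrow(built) %/% 12), 200)
  pick <- built[sample(nrow(built), min(n_minor, nrow(built))),
                , drop = FALSE]
  cell <- config$cell_size_m
  for (i in seq_len(nrow(pick))) {
    ctr <- c((pick[i, 2] - 0.5) * cell, (pick[i, 1] - 0.5) * cell)
    ang <- runif(1, 0, pi)
    len <- runif(1, 300, 800)
    from <- ctr - len / 2 * c(cos(ang), sin(ang))
    to <- ctr + len / 2 * c(cos(ang), sin(ang))
    from <- pmin(pmax(from, 0), c(w, h)); to <- pmin(pmax(to, 0), c(w, h))
    add_road("minor", jitter_line(from, to, n_vertex = 5, amp = 15))
  }

  # POIs concentrated in built-up land cover (cbi strongest)
  kinds <- c("church", "mosque", "hospital", "school", "restaurant",
             "market", "bar", "bus_station")
  kind_w <- c(0.18, 0.12, 0.06, 0.14, 0.16, 0.12, 0.12, 0.10)
  cls_w <- c(formal_residential = 2, informal_residential = 3,
             cbi = 6, other = 0.3)
  cell_w <- cls_w[rasters$land_cover$values] *
    (rasters$water$values == 0L)
  n_poi <- 240
  centers <- grid_centers(rasters$land_cover)
  idx <- sample(length(cell_w), n_poi, replace = TRUE, prob = cell_w)
  pois <- data.frame(
    x = centers[idx, 1] + runif(n_poi, -cell / 2, cell / 2),
    y = centers[idx, 2] + runif(n_poi, -cell / 2, cell / 2),
    kind = sample(kinds, n_poi, replace = TRUE, prob = kind_w),
    stringsAsFactors = FALSE)

  # buildings proportional to population density
  n_bld <- 1500
  bw <- rasters$pop_density$values * (rasters$water$values == 0L)
  bidx <- sample(length(bw), n_bld, replace = TRUE, prob = bw)
  buildings <- data.frame(
    x = centers[bidx, 1] + runif(n_bld, -cell / 2, cell / 2),
    y = centers[bidx, 2] + runif(n_bld, -cell / 2, cell / 2))

  # waterway centerline matching the raster river corridor
  ys <- (seq_len(nrow(rasters$water$values)) - 0.5) * cell
  river <- cbind(0.70 * w + 0.04 * w * sin(ys / h * 2 * pi), ys)
  waterways <- list(list(id = "river_01", class = "river", coords = river))

  out <- list(roads = roads, pois = pois, waterways = waterways,
              buildings = buildings, extent_m = config$extent_m)
  class(out) <- "vector_layers"
  out
}

#' Decompose polyline features into a segment matrix
#'
#' @param layers a `vector_layers` object (or any list of features with
#'   `class` and `coords`).
#' @param classes road classes to keep; `"all"` keeps every class.
#' @param what which layer to decompose, `"roads"` or `"waterways"`.
#' @return Numeric matrix with columns `x0, y0, x1, y1`, one row per
#'   segment (0 rows if no feature matches).
#' @export
road_segments <- function(layers, classes = "all", what = "roads") {
  feats <- layers[[what]]
  if (!identical(classes, "all"))
    feats <- Filter(function(f) f$class %in% classes, feats)
  if (length(feats) == 0)
    return(matrix(numeric(0), ncol = 4,
                  dimnames = list(NULL, c("x0", "y0", "x1", "y1"))))
  segs <- lapply(feats, function(f) {
    cc <- f$coords
    n <- nrow(cc)
    cbind(cc[-n, 1], cc[-n, 2], cc[-1, 1], cc[-1, 2])
  })
  out <- do.call(rbind, segs)
  colnames(out) <- c("x0", "y0", "x1", "y1")
  out
}

#' Sample monitoring sites by stratified random sampling
#'
#' Rotating sites are allocated across the four land-use strata according to
#' `strata_weights`, with `core_fraction` of them placed inside the core
#' zone (stratified within each zone). Fixed sites are spread evenly across
#' strata, alternating core and periphery. Sites are placed at a uniformly
#' jittered position inside a sampled cell of their stratum.
#'
#' @param config a [city_config()].
#' @param rasters output of [generate_covariate_rasters()].
#' @return data.frame with columns `site_id, x, y, site_type, stratum,
#'   in_core`.
#' @export
sample_sites <- function(config, rasters) {
  stopifnot(inherits(config, "city_config"),
            inherits(rasters, "covariate_rasters"))
  set.seed(derive_seed(config$seed, 3))
  lc <- rasters$land_cover
  classes <- lc$levels
  centers <- grid_centers(lc)
  code <- as.vector(lc$values)
  water <- as.vector(rasters$water$values) == 1L
  core <- in_core_zone(centers[, 1], centers[, 2], config)
  for (k in seq_along(classes)) {
    if (!any(code == k & !water))
      stop(sprintf("stratum '%s' absent from land_cover raster", classes[k]))
  }
  cell <- config$cell_size_m

  draw_in_stratum <- function(k, zone, n) {
    # zone: TRUE = core only, FALSE = periphery only, NA = anywhere
    ok <- code == k & !water
    if (!is.na(zone)) ok <- ok & (core == zone)
    pool <- which(ok)
    if (length(pool) == 0) pool <- which(code == k & !water)  # zone fallback
    idx <- sample(pool, n, replace = length(pool) < n)
    data.frame(
      x = centers[idx, 1] + runif(n, -cell / 2 + 1, cell / 2 - 1),
      y = centers[idx, 2] + runif(n, -cell / 2 + 1, cell / 2 - 1),
      stratum = classes[k], stringsAsFactors = FALSE)
  }

  # rotating: core_fraction into the core zone, remainder outside
  n_rot <- config$n_rotating_sites
  n_core <- round(config$core_fraction * n_rot)
  rot <- list()
  for (zone in c(TRUE, FALSE)) {
    nz <- if (zone) n_core else n_rot - n_core
    if (nz == 0) next
    per_stratum <- allocate_counts(config$strata_weights, nz)
    for (k in seq_along(classes)) {
      if (per_stratum[k] > 0)
        rot[[length(rot) + 1]] <- cbind(
          draw_in_stratum(k, zone, per_stratum[k]), zone = zone)
    }
  }
  rot <- if (length(rot)) do.call(rbind, rot) else
    data.frame(x = numeric(0), y = numeric(0), stratum = character(0),
               zone = logical(0))

  # fixed: even round-robin over strata, alternating zones
  n_fix <- config$n_fixed_sites
  fix <- list()
  if (n_fix > 0) {
    for (i in seq_len(n_fix)) {
      k <- ((i - 1) %% length(classes)) + 1
      zone <- i %% 2 == 0
      fix[[i]] <- cbind(draw_in_stratum(k, zone, 1), zone = zone)
    }
    fix <- do.call(rbind, fix)
  }

  mk <- function(d, type, prefix) {
    if (NROW(d) == 0) return(NULL)
    data.frame(site_id = sprintf("%s%03d", prefix, seq_len(nrow(d))),
               x = d$x, y = d$y, site_type = type, stratum = d$stratum,
               in_core = in_core_zone(d$x, d$y, config),
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk(fix, "fixed", "F"), mk(rot, "rotating", "R"))
  rownames(out) <- NULL
  out
}

#' Default ground-truth sound process
#'
#' The per-clip presence of each sound category is Bernoulli with a logistic
#' probability in three standardized local covariates: NDVI, log population
#' density, and major-road proximity `exp(-d/300 m)`. Coefficients encode
#' the structure the analysis assumes: road-transport loads positively on
#' road proximity, animal/insect sounds load on greenness and negatively on
#' roads (opposite sign to road-transport), music and speech load on
#' population density, geophysical nature is rare and skewed toward zero.
#' Day/night intercept offsets reproduce the diurnal contrasts (speech and
#' road sounds drop at night; animal sounds rise). The sound-level model is
#' `L = base + gain * exp(-d_major/tau) + noise`, with a fixed day-night
#' offset.
#'
#' @param rasters output of [generate_covariate_rasters()].
#' @param vectors output of [generate_vector_layers()].
#' @return List of class `ground_truth` holding the coefficient matrix
#'   (log-odds units), night offsets, standardized covariate fields
#'   ([sgrid]s), and the level model parameters.
#' @export
default_ground_truth <- function(rasters, vectors) {
  cell <- rasters$ndvi$cell
  centers <- grid_centers(rasters$ndvi)
  segs <- road_segments(vectors, "major")
  d_major <- cpp_min_dist_to_segments(centers, segs)
  road_prox <- exp(-d_major / 300)

  zfield <- function(v) {
    m <- mean(v); s <- max(sd(v), 1e-12)
    sgrid(matrix((v - m) / s, nrow = nrow(rasters$ndvi$values)), cell = cell)
  }
  fields <- list(
    ndvi = zfield(as.vector(rasters$ndvi$values)),
    pop = zfield(log(as.vector(rasters$pop_density$values))),
    road = zfield(road_prox))

  coefs <- rbind(                     # intercept, ndvi, pop, road (log-odds)
    road_transport     = c( 0.9, -0.4, 0.20,  1.2),
    animal_insect      = c( 0.4,  0.8, -0.30, -1.0),
    music              = c(-2.4, -0.2, 0.70,  0.1),
    speech             = c(-1.3, -0.3, 0.80,  0.2),
    aircraft           = c(-3.5,  0.0, 0.00,  0.0),
    geophysical_nature = c(-6.3,  0.8, -0.20, -0.2),
    other              = c(-0.8,  0.0, 0.00,  0.0))
  colnames(coefs) <- c("intercept", "ndvi", "pop", "road")
  night_offset <- c(road_transport = -1.0, animal_insect = 0.5,
                    music = -0.3, speech = -1.5, aircraft = 0.0,
                    geophysical_nature = 0.3, other = 0.0)

  structure(list(
    coefs = coefs, night_offset = night_offset, fields = fields,
    level_model = list(base_dba = 55, gain_dba = 14, tau_m = 250,
                       night_offset_dba = 7, noise_sd_dba = 1.5)),
    class = "ground_truth")
}

gt_covariates_at <- function(ground_truth, x, y) {
  cbind(ndvi = grid_value_at(ground_truth$fields$ndvi, x, y),
        pop = grid_value_at(ground_truth$fields$pop, x, y),
        road = grid_value_at(ground_truth$fields$road, x, y))
}

#' Closed-form expected prevalence under the ground truth
#'
#' The percentage of clips in which a category is expected to be present at
#' a site: `100 * logistic(intercept + coef . z(site) + night_offset)`.
#' This is the parameter-recovery target the fitted LUR models are checked
#' against.
#'
#' @param ground_truth a [default_ground_truth()] object (or one with the
#'   same structure).
#' @param site a one-row data.frame (or list) with `x` and `y`, or a
#'   multi-row site table.
#' @param category category name (row of the coefficient matrix).
#' @param period `"day"` or `"night"`.
#' @return Expected prevalence in percent, in `[0, 100]`; vectorized over
#'   sites.
#' @export
expected_prevalence <- function(ground_truth, site, category, period) {
  stopifnot(category %in% rownames(ground_truth$coefs),
            period %in% c("day", "night"))
  z <- gt_covariates_at(ground_truth, site$x, site$y)
  b <- ground_truth$coefs[category, ]
  eta <- b["intercept"] + z %*% b[c("ndvi", "pop", "road")]
  if (period == "night") eta <- eta + ground_truth$night_offset[category]
  as.vector(100 * stats::plogis(eta))
}

#' Simulate per-clip sound-class detections
#'
#' Emulates an intermittent audio recorder and top-3 classifier: one 10 s
#' clip every 10 minutes (144 clips per full site-day). Per clip, each
#' sound category is present independently with its logistic ground-truth
#' probability; each present category emits one representative fine class
#' label; when more than three categories fire, the three with the largest
#' sampled prominence draws are kept (mimicking a classifier that returns
#' only its top three classes).
#'
#' @param sites site table from [sample_sites()].
#' @param ground_truth a [default_ground_truth()] object.
#' @param config a [city_config()].
#' @param ontology fine-class vocabulary, a [default_ontology()]-style
#'   mapping used to pick representative labels per category.
#' @return data.table with columns `site_id, timestamp` (POSIXct UTC,
#'   minute resolution) and `class1, class2, class3` (NA when fewer than
#'   three categories present; all NA for a silent clip).
#' @export
simulate_clip_labels <- function(sites, ground_truth, config,
                                 ontology = default_ontology()) {
  if (NROW(sites) == 0) {
    return(data.table(site_id = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      class1 = character(0), class2 = character(0),
                      class3 = character(0)))
  }
  set.seed(derive_seed(config$seed, 4))
  cats <- rownames(ground_truth$coefs)
  # representative fine labels per category from the ontology
  fine_by_cat <- split(names(ontology$map), unname(ontology$map))

  minutes <- (0:143) * 10               # slots within a day
  hour <- (minutes %/% 60)
  is_day_slot <- hour >= 6 & hour < 22

  start <- as.POSIXct(paste(config$campaign_start, "00:00:00"), tz = "UTC")
  rot_ids <- which(sites$site_type == "rotating")

  out <- vector("list", nrow(sites))
  for (si in seq_len(nrow(sites))) {
    st <- sites[si, ]
    n_days <- if (st$site_type == "fixed") config$campaign_days_fixed
              else config$campaign_days_rotating
    # rotating deployments staggered in weekly batches of 10 recorders
    day0 <- if (st$site_type == "fixed") 0L else
      (((match(si, rot_ids) - 1L) %/% 10L) *
         config$campaign_days_rotating)
    n_clips <- n_days * 144L
    ts <- start + rep((day0 + seq_len(n_days) - 1L) * 86400, each = 144) +
      rep(minutes * 60, times = n_days)
    day_flag <- rep(is_day_slot, times = n_days)

    p_day <- vapply(cats, function(cc)
      expected_prevalence(ground_truth, st, cc, "day") / 100, 0)
    p_night <- vapply(cats, function(cc)
      expected_prevalence(ground_truth, st, cc, "night") / 100, 0)
    p <- outer(day_flag, p_day) ; p[!day_flag, ] <- rep(p_night,
                                      each = sum(!day_flag))
    present <- matrix(runif(n_clips * length(cats)), n_clips) < p
    prom <- matrix(runif(n_clips * length(cats)), n_clips)
    prom[!present] <- -Inf

    # top-3 truncation: when > 3 categories fire, keep the three with the
    # largest prominence draws
    K <- length(cats)
    kept <- present
    for (r in which(rowSums(present) > 3)) {
      idx <- which(present[r, ])
      drop <- idx[order(prom[r, idx], decreasing = TRUE)][-(1:3)]
      kept[r, drop] <- FALSE
    }
    # rank kept categories by prominence (1 = most prominent); prominence
    # draws are continuous so ties have probability zero
    rank_m <- matrix(0L, n_clips, K)
    for (j in seq_len(K)) {
      rj <- rep(1L, n_clips)
      for (l in seq_len(K)) {
        if (l != j) rj <- rj + (kept[, l] & prom[, l] > prom[, j])
      }
      rank_m[, j] <- ifelse(kept[, j], rj, 0L)
    }
    lab <- matrix(NA_character_, n_clips, 3)
    for (j in seq_len(K)) {
      fine <- fine_by_cat[[cats[j]]]
      for (s in 1:3) {
        rows <- which(rank_m[, j] == s)
        if (length(rows))
          lab[rows, s] <- sample(fine, length(rows), replace = TRUE)
      }
    }
    out[[si]] <- data.table(site_id = st$site_id, timestamp = ts,
                            class1 = lab[, 1], class2 = lab[, 2],
                            class3 = lab[, 3])
  }
  rbindlist(out)
}

#' Simulate day and night sound-level surfaces
#'
#' `L = base + gain * exp(-d_major / tau) + noise`: levels decay with
#' distance from major roads; one coherent noise field is shared by both
#' periods, so `L_day - L_night` equals the night offset everywhere and
#' `L_day >= L_night` cell-wise under any non-negative offset.
#'
#' @param rasters output of [generate_covariate_rasters()].
#' @param vectors output of [generate_vector_layers()].
#' @param ground_truth a [default_ground_truth()] object (carries the level
#'   model parameters).
#' @param config a [city_config()] (for the seed).
#' @return List with [sgrid]s `L_day` and `L_night` in dBA.
#' @export
simulate_level_surface <- function(rasters, vectors, ground_truth, config) {
  set.seed(derive_seed(config$seed, 5))
  lm <- ground_truth$level_model
  g <- rasters$ndvi
  centers <- grid_centers(g)
  segs <- road_segments(vectors, "major")
  d <- cpp_min_dist_to_segments(centers, segs)
  noise <- lm$noise_sd_dba *
    smooth_noise(nrow(g$values), ncol(g$values), k = 2)
  l_day <- matrix(lm$base_dba + lm$gain_dba * exp(-d / lm$tau_m),
                  nrow(g$values)) + noise
  list(L_day = sgrid(l_day, cell = g$cell),
       L_night = sgrid(l_day - lm$night_offset_dba, cell = g$cell))
}

#' Generate a complete synthetic city
#'
#' Convenience wrapper running every generator stage with one seed.
#'
#' @param config a [city_config()].
#' @param ontology fine-class vocabulary for clip labels.
#' @return List with `config`, `rasters`, `vectors`, `sites`,
#'   `ground_truth`, `clips` and `levels`.
#' @export
simulate_city <- function(config = city_config(),
                          ontology = default_ontology()) {
  rasters <- generate_covariate_rasters(config)
  vectors <- generate_vector_layers(config, rasters)
  sites <- sample_sites(config, rasters)
  gt <- default_ground_truth(rasters, vectors)
  clips <- simulate_clip_labels(sites, gt, config, ontology)
  levels <- simulate_level_surface(rasters, vectors, gt, config)
  list(config = config, rasters = rasters, vectors = vectors, sites = sites,
       ground_truth = gt, clips = clips, levels = levels)
}
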