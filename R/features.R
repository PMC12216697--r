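#' Default spatial predictor inventory
#'
#' The buffer-based predictor set as data, editable before fitting: total
#' road length per class (major, secondary/tertiary, minor, all), counts of
#' eight POI kinds, building count, waterway length, mean NDVI, mean
#' population density, land-cover composition shares, elevation (point
#' value at the target), and distance to the nearest major road. Buffer
#' radii are 50, 100, 200 and 500 m. `period` marks a-priori applicability:
#' schools are considered sound-producing in the daytime only; every other
#' predictor applies to both periods.
#'
#' @param radii candidate buffer radii in meters.
#' @return data.frame of class `predictor_specs` with columns `name,
#'   source, filter, statistic, radii, period`.
#' @export
default_predictor_specs <- function(radii = c(50, 100, 200, 500)) {
  rstr <- paste(radii, collapse = ",")
  spec <- function(name, source, filter, statistic, r = rstr,
                   period = "both")
    data.frame(name = name, source = source, filter = filter,
               statistic = statistic, radii = r, period = period,
               stringsAsFactors = FALSE)
  rows <- list(
    spec("road_major", "roads", "major", "length_sum"),
    spec("road_secondary_tertiary", "roads", "secondary_tertiary",
         "length_sum"),
    spec("road_minor", "roads", "minor", "length_sum"),
    spec("road_all", "roads", "all", "length_sum"))
  pois <- c("church", "mosque", "hospital", "school", "restaurant",
            "market", "bar", "bus_station")
  for (k in pois)
    rows[[length(rows) + 1]] <- spec(
      paste0("poi_", k), "pois", k, "count",
      period = if (k == "school") "day" else "both")
  rows <- c(rows, list(
    spec("building", "buildings", NA, "count"),
    spec("waterway", "waterways", "all", "length_sum"),
    spec("ndvi", "ndvi", NA, "raster_mean"),
    spec("pop_density", "pop_density", NA, "raster_mean")))
  for (cl in landcover_classes())
    rows[[length(rows) + 1]] <- spec(
      paste0("lc_", cl), "land_cover", cl, "composition_share")
  rows <- c(rows, list(
    spec("elevation", "elevation", NA, "point_value", r = ""),
    spec("dist_major_road", "roads", "major", "distance_nearest", r = "")))
  out <- do.call(rbind, rows)
  class(out) <- c("predictor_specs", class(out))
  out
}

spec_radii <- function(spec_row) {
  if (is.na(spec_row$radii) || spec_row$radii == "") return(numeric(0))
  as.numeric(strsplit(spec_row$radii, ",")[[1]])
}

# column names a spec row expands to, radii ascending
spec_columns <- function(spec_row) {
  r <- spec_radii(spec_row)
  if (length(r) == 0) spec_row$name
  else paste0(spec_row$name, "@", sort(r))
}

check_radius <- function(radius) {
  if (any(!is.finite(radius)) || any(radius <= 0))
    stop("buffer radius must be positive")
}

as_center <- function(center) {
  center <- as.numeric(center)
  stopifnot(length(center) == 2)
  matrix(center, ncol = 2)
}

#' Total polyline length inside a circular buffer
#'
#' Sum of the geometric intersection of line segments with the closed disk
#' of the given radius (planar Euclidean meters), computed analytically per
#' segment.
#'
#' @param lines segment matrix with columns `x0, y0, x1, y1` (see
#'   [road_segments()]).
#' @param center numeric `(x, y)` of the buffer center.
#' @param radius buffer radius in meters; must be positive.
#' @return Length in meters (0 if no line enters the disk).
#' @export
line_length_in_buffer <- function(lines, center, radius) {
  check_radius(radius)
  if (NROW(lines) == 0) return(0)
  as.numeric(cpp_line_lengths(as.matrix(lines), as_center(center), radius))
}

#' Count points inside a circular buffer
#'
#' Boundary inclusive: a point at exactly `radius` from the center counts
#' (closed-disk convention).
#'
#' @param points two-column matrix or data.frame of `(x, y)`.
#' @inheritParams line_length_in_buffer
#' @return Integer count.
#' @export
point_count_in_buffer <- function(points, center, radius) {
  check_radius(radius)
  if (NROW(points) == 0) return(0L)
  pts <- as.matrix(as.data.frame(points)[, c("x", "y")])
  as.integer(cpp_point_counts(pts, as_center(center), radius))
}

#' Mean raster value inside a circular buffer
#'
#' Mean over cells whose centers lie in the closed disk (cell-center rule,
#' not area weighting). A disk containing no cell center is a structural
#' error and yields `NA` with a warning.
#'
#' @param grid an [sgrid].
#' @inheritParams line_length_in_buffer
#' @return Mean cell value.
#' @export
raster_mean_in_buffer <- function(grid, center, radius) {
  check_radius(radius)
  res <- cpp_raster_mean_in_disk(grid$values, grid$xmin, grid$ymin,
                                 grid$cell, as_center(center), radius)
  if (res$n_cells[1] == 0) {
    warning("buffer contains no raster cell centers; returning NA")
    return(NA_real_)
  }
  res$mean[1]
}

#' Land-cover composition shares inside a circular buffer
#'
#' Per-class share of cell centers in the closed disk; shares sum to 1.
#'
#' @param grid categorical [sgrid] with `levels`.
#' @inheritParams line_length_in_buffer
#' @return Named numeric vector of shares, one per class.
#' @export
landcover_composition_in_buffer <- function(grid, center, radius) {
  check_radius(radius)
  counts <- cpp_class_counts_in_disk(grid$values, length(grid$levels),
                                     grid$xmin, grid$ymin, grid$cell,
                                     as_center(center), radius)
  n <- sum(counts)
  if (n == 0) {
    warning("buffer contains no raster cell centers; returning NA shares")
    return(setNames(rep(NA_real_, length(grid$levels)), grid$levels))
  }
  setNames(as.numeric(counts) / n, grid$levels)
}

#' Distance to the nearest major road
#'
#' Minimum Euclidean distance from the target to any major-class road
#' polyline.
#'
#' @param center numeric `(x, y)`.
#' @param roads a `vector_layers` object or a major-road segment matrix.
#' @return Distance in meters.
#' @export
distance_to_nearest_major_road <- function(center, roads) {
  segs <- if (inherits(roads, "vector_layers"))
    road_segments(roads, "major") else as.matrix(roads)
  if (NROW(segs) == 0) stop("no major roads in the road layer")
  as.numeric(cpp_min_dist_to_segments(as_center(center), segs))
}

#' Build the buffer-feature matrix for sites or grid cells
#'
#' One column per (predictor, radius), named `name@radius`, plus unbuffered
#' columns (elevation point value, distance to nearest major road). Column
#' order is deterministic (spec order, radii ascending) and identical for
#' training sites and the prediction grid, which guarantees train/predict
#' schema identity. Empty buffers yield 0 for counts and lengths (a real
#' absence); an empty raster-mean disk is a structural error.
#'
#' @param targets data.frame with an id column (`site_id` or `cell_id`)
#'   and coordinates `x, y`.
#' @param layers list with elements `rasters` (a `covariate_rasters`) and
#'   `vectors` (a `vector_layers`).
#' @param specs a [default_predictor_specs()]-style data.frame.
#' @return data.frame of class `feature_matrix`: the id column followed by
#'   feature columns; the spec table is attached as attribute `"specs"`.
#' @export
build_feature_matrix <- function(targets, layers,
                                 specs = default_predictor_specs()) {
  id_col <- intersect(c("site_id", "cell_id"), names(targets))[1]
  if (is.na(id_col)) stop("targets need a site_id or cell_id column")
  centers <- as.matrix(targets[, c("x", "y")])
  rasters <- layers$rasters
  vectors <- layers$vectors

  seg_cache <- new.env(parent = emptyenv())
  get_segs <- function(what, filter) {
    key <- paste(what, filter)
    if (is.null(seg_cache[[key]])) {
      if (is.null(vectors[[what]]))
        stop(sprintf("feature spec references missing layer '%s'", what))
      cls <- if (is.na(filter) || filter == "all") "all" else filter
      seg_cache[[key]] <- road_segments(vectors, cls, what = what)
    }
    seg_cache[[key]]
  }
  get_layer <- function(source) {
    if (!is.null(rasters[[source]])) return(rasters[[source]])
    if (!is.null(vectors[[source]])) return(vectors[[source]])
    stop(sprintf("feature spec references missing layer '%s'", source))
  }

  cols <- list()
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    radii <- sort(spec_radii(sp))
    vals <- switch(
      sp$statistic,
      length_sum = {
        segs <- get_segs(sp$source, sp$filter)
        if (NROW(segs) == 0) matrix(0, nrow(centers), length(radii))
        else cpp_line_lengths(segs, centers, radii)
      },
      count = {
        layer <- get_layer(sp$source)
        pts <- if (!is.na(sp$filter) && "kind" %in% names(layer))
          layer[layer$kind == sp$filter, , drop = FALSE] else layer
        pts <- as.matrix(as.data.frame(pts)[, c("x", "y")])
        if (NROW(pts) == 0) matrix(0L, nrow(centers), length(radii))
        else cpp_point_counts(pts, centers, radii)
      },
      raster_mean = {
        g <- get_layer(sp$source)
        m <- sapply(radii, function(r) {
          res <- cpp_raster_mean_in_disk(g$values, g$xmin, g$ymin, g$cell,
                                         centers, r)
          if (any(res$n_cells == 0))
            stop(sprintf("empty raster-mean buffer for '%s' at %g m",
                         sp$name, r))
          res$mean
        })
        matrix(m, nrow = nrow(centers))
      },
      composition_share = {
        g <- get_layer(sp$source)
        k <- match(sp$filter, g$levels)
        if (is.na(k)) stop(sprintf("unknown land-cover class '%s'",
                                   sp$filter))
        m <- sapply(radii, function(r) {
          counts <- cpp_class_counts_in_disk(g$values, length(g$levels),
                                             g$xmin, g$ymin, g$cell,
                                             centers, r)
          tot <- rowSums(counts)
          if (any(tot == 0))
            stop(sprintf("empty composition buffer for '%s' at %g m",
                         sp$name, r))
          counts[, k] / tot
        })
        matrix(m, nrow = nrow(centers))
      },
      point_value = {
        g <- get_layer(sp$source)
        matrix(grid_value_at(g, centers[, 1], centers[, 2]), ncol = 1)
      },
      distance_nearest = {
        segs <- get_segs(sp$source, sp$filter)
        if (NROW(segs) == 0)
          stop(sprintf("no '%s' features for distance predictor '%s'",
                       sp$filter, sp$name))
        matrix(cpp_min_dist_to_segments(centers, segs), ncol = 1)
      },
      stop(sprintf("unknown statistic '%s'", sp$statistic)))
    colnames(vals) <- spec_columns(sp)
    cols[[i]] <- vals
  }
  out <- data.frame(targets[[id_col]], do.call(cbind, cols),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[1] <- id_col
  attr(out, "specs") <- specs
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Write and read a feature matrix with its spec sidecar
#'
#' The matrix goes to CSV; the predictor specs and exact column order go to
#' a JSON sidecar (`<path>.json`), so downstream stages can verify schema
#' identity.
#'
#' @param fm a [build_feature_matrix()] result.
#' @param path CSV file path.
#' @return `read_feature_matrix` returns the feature matrix; the writer
#'   returns `path` invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  fwrite(as.data.table(as.data.frame(fm)), path)
  sidecar <- list(columns = names(fm),
                  specs = as.data.frame(attr(fm, "specs")))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  dt <- as.data.frame(fread(path, check.names = FALSE))
  sidecar <- jsonlite::read_json(paste0(path, ".json"),
                                 simplifyVector = TRUE)
  if (!identical(names(dt), sidecar$columns))
    stop("feature matrix columns do not match the spec sidecar")
  sp <- as.data.frame(sidecar$specs, stringsAsFactors = FALSE)
  class(sp) <- c("predictor_specs", class(sp))
  attr(dt, "specs") <- sp
  class(dt) <- c("feature_matrix", class(dt))
  dt
}
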