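#' GeoJSON interchange for vector layers
#'
#' Polyline layers (roads, waterways) are written as LineString features
#' with `id` and `class` properties; point layers (POIs, buildings) as
#' Point features with their attribute columns. Coordinates are the planar
#' meters of the city frame (stored as-is; no CRS transformation).
#'
#' @param features list of polyline features (`list(id, class, coords)`)
#'   or a data.frame of points.
#' @param path output file.
#' @return `read_geojson` returns a feature list or data.frame matching
#'   what was written; writers return `path` invisibly.
#' @export
write_geojson <- function(features, path) {
  if (is.data.frame(features)) {
    feats <- lapply(seq_len(nrow(features)), function(i) {
      props <- as.list(features[i, setdiff(names(features), c("x", "y")),
                                drop = FALSE])
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(features$x[i], features$y[i])),
           properties = props)
    })
  } else {
    feats <- lapply(features, function(f) {
      list(type = "Feature",
           geometry = list(type = "LineString",
                           coordinates = unname(
                             lapply(seq_len(nrow(f$coords)),
                                    function(i) f$coords[i, ]))),
           properties = list(id = f$id, class = f$class))
    })
  }
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geojson
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  if (length(feats) == 0) return(list())
  if (feats[[1]]$geometry$type == "Point") {
    rows <- lapply(feats, function(f) {
      cc <- unlist(f$geometry$coordinates)
      out <- data.frame(x = cc[1], y = cc[2])
      if (length(f$properties))
        out <- cbind(out, as.data.frame(f$properties,
                                        stringsAsFactors = FALSE))
      out
    })
    do.call(rbind, rows)
  } else {
    lapply(feats, function(f) {
      cc <- do.call(rbind, lapply(f$geometry$coordinates, unlist))
      list(id = f$properties$id, class = f$properties$class, coords = cc)
    })
  }
}

#' Write and read the full layer set of a synthetic city
#'
#' Rasters go to ESRI ASCII grids, vectors to GeoJSON, in one directory.
#' This is the serialized form each pipeline stage can be re-run from.
#'
#' @param rasters a `covariate_rasters` object.
#' @param vectors a `vector_layers` object.
#' @param dir directory (created if needed).
#' @return `read_layers` returns `list(rasters, vectors)`; the writer
#'   returns `dir` invisibly.
#' @export
write_layers <- function(rasters, vectors, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("ndvi", "pop_density", "land_cover", "elevation", "water"))
    write_asc(rasters[[nm]], file.path(dir, paste0(nm, ".asc")))
  write_geojson(vectors$roads, file.path(dir, "roads.geojson"))
  write_geojson(vectors$pois, file.path(dir, "pois.geojson"))
  write_geojson(vectors$waterways, file.path(dir, "waterways.geojson"))
  write_geojson(vectors$buildings, file.path(dir, "buildings.geojson"))
  invisible(dir)
}

#' @rdname write_layers
#' @export
read_layers <- function(dir) {
  rasters <- list(
    ndvi = read_asc(file.path(dir, "ndvi.asc")),
    pop_density = read_asc(file.path(dir, "pop_density.asc")),
    land_cover = read_asc(file.path(dir, "land_cover.asc"),
                          levels = landcover_classes()),
    elevation = read_asc(file.path(dir, "elevation.asc")),
    water = read_asc(file.path(dir, "water.asc")))
  rasters$land_cover$values <-
    matrix(as.integer(rasters$land_cover$values),
           nrow = nrow(rasters$land_cover$values))
  rasters$water$values <- matrix(as.integer(rasters$water$values),
                                 nrow = nrow(rasters$water$values))
  class(rasters) <- "covariate_rasters"
  vectors <- list(
    roads = read_geojson(file.path(dir, "roads.geojson")),
    pois = read_geojson(file.path(dir, "pois.geojson")),
    waterways = read_geojson(file.path(dir, "waterways.geojson")),
    buildings = read_geojson(file.path(dir, "buildings.geojson")))
  ext <- grid_extent(rasters$ndvi)
  vectors$extent_m <- unname(c(ext["width"], ext["height"]))
  class(vectors) <- "vector_layers"
  list(rasters = rasters, vectors = vectors)
}

#' Site table CSV interchange
#'
#' @param sites site table from [sample_sites()].
#' @param path file path.
#' @return The reader returns the site data.frame; the writer returns
#'   `path` invisibly.
#' @export
write_sites_csv <- function(sites, path) {
  fwrite(as.data.table(sites), path)
  invisible(path)
}

#' @rdname write_sites_csv
#' @export
read_sites_csv <- function(path) {
  as.data.frame(fread(path))
}

#' Serialize a fitted LUR model to JSON
#'
#' A text archive of the trained forest (node arrays), the buffer
#' selection, the spec and the training-response range — everything needed
#' to predict on new feature matrices. Training data and in-bag records
#' are not serialized, so permutation importance requires the in-memory
#' fit.
#'
#' @param fit a [fit_lur()] object.
#' @param path output `.json` file.
#' @return `read_fitted_lur` returns a `fitted_lur` usable with
#'   [predict_surface()]; the writer returns `path` invisibly.
#' @export
write_fitted_lur <- function(fit, path) {
  f <- fit$model$forest
  payload <- list(
    spec = unclass(fit$spec),
    columns = fit$selection$columns,
    choice = fit$selection$choice,
    reliable = fit$reliable,
    y_range = fit$model$y_range,
    n_trees = fit$model$n_trees, mtry = fit$model$mtry,
    min_node = fit$model$min_node, seed = fit$model$seed,
    forest = list(var = f$var, thresh = f$thresh, left = f$left,
                  right = f$right, value = f$value, roots = f$roots))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fitted_lur
#' @export
read_fitted_lur <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  forest <- list(var = as.integer(p$forest$var),
                 thresh = as.numeric(p$forest$thresh),
                 left = as.integer(p$forest$left),
                 right = as.integer(p$forest$right),
                 value = as.numeric(p$forest$value),
                 roots = as.integer(p$forest$roots),
                 inbag = matrix(integer(0), 0, 0),
                 n_trees = p$n_trees, p = length(p$columns))
  model <- structure(list(forest = forest, features = p$columns,
                          x = NULL, y = NULL, y_range = p$y_range,
                          n_trees = p$n_trees, mtry = p$mtry,
                          min_node = p$min_node, seed = p$seed),
                     class = "rf_model")
  spec <- structure(p$spec, class = "lur_spec")
  selection <- structure(list(columns = p$columns,
                              choice = as.data.frame(p$choice),
                              importance = NULL),
                         class = "buffer_selection")
  structure(list(spec = spec, selection = selection, model = model,
                 train = NULL, reliable = p$reliable),
            class = "fitted_lur")
}
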