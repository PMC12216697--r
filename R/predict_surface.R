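#' Build the prediction grid
#'
#' Tiles the extent with square cells (default 50 m) without gaps or
#' overlap; cell centers sit at cell midpoints. Cell order is column-major
#' with rows running south to north, matching the [sgrid] value layout.
#'
#' @param extent numeric `(width, height)` in meters; must be divisible by
#'   `cell_size`.
#' @param cell_size cell edge length in meters.
#' @return data.frame of class `prediction_grid` with `cell_id, x, y`;
#'   grid geometry in attributes `nrow, ncol, cell`.
#' @export
build_grid <- function(extent, cell_size = 50) {
  extent <- as.numeric(extent)
  if (length(extent) == 1) extent <- rep(extent, 2)
  if (any(extent %% cell_size != 0))
    stop("extent must be divisible by the cell size")
  nc <- extent[1] %/% cell_size
  nr <- extent[2] %/% cell_size
  x <- (rep(seq_len(nc), each = nr) - 0.5) * cell_size
  y <- (rep(seq_len(nr), times = nc) - 0.5) * cell_size
  out <- data.frame(cell_id = seq_len(nr * nc), x = x, y = y)
  attr(out, "nrow") <- nr; attr(out, "ncol") <- nc
  attr(out, "cell") <- cell_size
  class(out) <- c("prediction_grid", class(out))
  out
}

#' Mask out-of-sample grid cells
#'
#' Cells where the monitoring sites are not representative are excluded
#' from prediction, for three accumulating reasons: `no_roads` (no road
#' polyline of any class intersects the cell polygon), `water` (the cell
#' is fully water), and `natural_only` (every land-cover cell within it is
#' class "other" and no road intersects). A cell crossed by any road is
#' never masked.
#'
#' @param grid a [build_grid()] result.
#' @param layers list with `rasters` (`covariate_rasters`) and `vectors`
#'   (`vector_layers`).
#' @return The grid with added logical columns `no_roads, water,
#'   natural_only, masked` and a `mask_reason` string column
#'   (`""` for unmasked cells, reasons joined by `+`).
#' @export
compute_mask <- function(grid, layers) {
  cell <- attr(grid, "cell")
  centers <- as.matrix(grid[, c("x", "y")])
  segs <- road_segments(layers$vectors, "all")
  has_road <- as.logical(cpp_any_segment_in_cell(segs, centers, cell / 2))
  water <- grid_value_at(layers$rasters$water, grid$x, grid$y) == 1
  lc_other <- grid_value_at(layers$rasters$land_cover, grid$x, grid$y) ==
    match("other", layers$rasters$land_cover$levels)

  grid$no_roads <- !has_road
  grid$water <- water
  grid$natural_only <- lc_other & !has_road
  grid$masked <- grid$no_roads | grid$water | grid$natural_only
  reasons <- cbind(no_roads = grid$no_roads, water = grid$water,
                   natural_only = grid$natural_only)
  grid$mask_reason <- apply(reasons, 1, function(r)
    paste(colnames(reasons)[r], collapse = "+"))
  grid
}

#' Predict a sound-type prevalence surface
#'
#' Applies a fitted LUR model to the prediction grid's feature matrix,
#' leaving masked cells as no-data. Forest averaging bounds predictions by
#' the training-response range, so values are finite and within
#' `[0, 100]`.
#'
#' @param fit a [fit_lur()] model.
#' @param grid_features [build_feature_matrix()] computed at the grid
#'   cell centers (same specs as the training sites).
#' @param grid a masked grid from [compute_mask()].
#' @return Object of class `surface`: per-cell values (NA on masked
#'   cells), the grid, and the model's category/period.
#' @export
predict_surface <- function(fit, grid_features, grid) {
  if (is.null(grid$masked)) stop("grid has no mask; run compute_mask first")
  fm <- as.data.frame(grid_features)
  idx <- match(grid$cell_id, fm$cell_id)
  if (anyNA(idx)) stop("grid cells missing from the grid feature matrix")
  values <- rep(NA_real_, nrow(grid))
  open <- which(!grid$masked)
  if (length(open))
    values[open] <- predict(fit, fm[idx[open], , drop = FALSE])
  structure(list(category = fit$spec$category, period = fit$spec$period,
                 values = values, grid = grid,
                 reliable = fit$reliable), class = "surface")
}

#' @export
print.surface <- function(x, ...) {
  cat(sprintf("<surface> %s / %s: %d cells (%d predicted, %d masked)\n",
              x$category, x$period, length(x$values),
              sum(!is.na(x$values)), sum(is.na(x$values))))
  invisible(x)
}

#' Convert a surface to a raster grid
#'
#' @param surface a [predict_surface()] (or index) surface.
#' @return An [sgrid] with NA on masked cells, suitable for [write_asc()].
#' @export
surface_to_sgrid <- function(surface) {
  g <- surface$grid
  sgrid(matrix(surface$values, nrow = attr(g, "nrow")),
        cell = attr(g, "cell"))
}

#' Zonal assignment of grid cells for surface summaries
#'
#' Builds the standard reporting zones: the whole area, the core zone, and
#' road-proximity classes (nearest road class within `proximity_m` of the
#' cell center; cells near no road fall in `"no_road_nearby"`).
#'
#' @param grid a [build_grid()] result.
#' @param config a [city_config()] (defines the core zone).
#' @param vectors a `vector_layers` object.
#' @param proximity_m distance defining "near" a road (default 100 m).
#' @return Named list of logical vectors over grid cells, one per zone.
#' @export
surface_zones <- function(grid, config, vectors, proximity_m = 100) {
  centers <- as.matrix(grid[, c("x", "y")])
  core <- in_core_zone(grid$x, grid$y, config)
  classes <- c("major", "secondary_tertiary", "minor")
  d <- sapply(classes, function(cl) {
    segs <- road_segments(vectors, cl)
    if (NROW(segs) == 0) rep(Inf, nrow(grid))
    else cpp_min_dist_to_segments(centers, segs)
  })
  nearest <- classes[max.col(-d)]
  near_any <- apply(d, 1, min) <= proximity_m
  zones <- list(whole_area = rep(TRUE, nrow(grid)), core = core)
  for (cl in classes)
    zones[[paste0("near_", cl)]] <- near_any & nearest == cl
  zones
}

#' Summarize a surface by zone
#'
#' Order statistics (median, quartiles, min, max) over the unmasked cells
#' of each zone. A zone with no unmasked cells is flagged with a warning
#' and produces no summary row.
#'
#' @param surface a [predict_surface()] surface.
#' @param zones named list of logical vectors over grid cells (see
#'   [surface_zones()]); default is the whole area.
#' @return data.frame with `zone, n_cells, min, q1, median, q3, max`.
#' @export
summarize_surface <- function(surface,
                              zones = list(whole_area =
                                             rep(TRUE,
                                                 length(surface$values)))) {
  rows <- lapply(names(zones), function(zn) {
    v <- surface$values[zones[[zn]]]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      warning(sprintf("zone '%s' has no unmasked cells", zn))
      return(NULL)
    }
    q <- unname(quantile(v, c(0, 0.25, 0.5, 0.75, 1)))
    data.frame(zone = zn, n_cells = length(v), min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
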