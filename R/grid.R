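#' Planar raster grid
#'
#' A minimal raster container on a projected planar frame in meters. The
#' value matrix is stored with row 1 as the southernmost row and column 1 as
#' the westernmost column; the center of cell `[i, j]` is at
#' `(xmin + (j - 0.5) * cell, ymin + (i - 0.5) * cell)`. All layers produced
#' by the synthetic-city generator share one frame so buffer geometry is
#' exact Euclidean.
#'
#' @param values numeric (or integer) matrix of cell values.
#' @param xmin,ymin coordinates of the grid origin (south-west corner), m.
#' @param cell cell edge length in meters.
#' @param levels optional character vector of class labels for categorical
#'   grids coded as integers `1..length(levels)`.
#' @return An object of class `sgrid`.
#' @export
sgrid <- function(values, xmin = 0, ymin = 0, cell, levels = NULL) {
  stopifnot(is.matrix(values), cell > 0)
  structure(
    list(values = values, xmin = xmin, ymin = ymin, cell = cell,
         levels = levels),
    class = "sgrid")
}

#' @export
print.sgrid <- function(x, ...) {
  cat(sprintf("<sgrid> %d x %d cells, %g m resolution, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell, x$xmin, x$ymin))
  if (!is.null(x$levels))
    cat("  classes:", paste(x$levels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.sgrid <- function(x) dim(x$values)

grid_extent <- function(g) {
  c(width = ncol(g$values) * g$cell, height = nrow(g$values) * g$cell)
}

#' Cell-center coordinates of a grid
#'
#' @param g an [sgrid].
#' @return A two-column matrix `(x, y)` of all cell centers, in column-major
#'   cell order (matching `as.vector(g$values)`).
#' @export
grid_centers <- function(g) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  x <- g$xmin + (rep(seq_len(nc), each = nr) - 0.5) * g$cell
  y <- g$ymin + (rep(seq_len(nr), times = nc) - 0.5) * g$cell
  cbind(x = x, y = y)
}

#' Look up grid values at point locations
#'
#' Points are assigned to the cell containing them (cell edges belong to the
#' cell to their north-east, except at the grid border).
#'
#' @param g an [sgrid].
#' @param x,y point coordinates in meters.
#' @return Vector of cell values at the points.
#' @export
grid_value_at <- function(g, x, y) {
  nr <- nrow(g$values); nc <- ncol(g$values)
  j <- pmin(pmax(floor((x - g$xmin) / g$cell) + 1, 1), nc)
  i <- pmin(pmax(floor((y - g$ymin) / g$cell) + 1, 1), nr)
  g$values[cbind(i, j)]
}

#' Read and write ESRI ASCII grid files
#'
#' Plain-text raster interchange. `NA` is written as the nodata value
#' (-9999). Categorical grids lose their labels on disk; pass `levels` to
#' restore them on read.
#'
#' @param g an [sgrid].
#' @param path file path (conventionally `.asc`).
#' @param digits significant digits written (full precision by default).
#' @return `read_asc` returns an [sgrid]; `write_asc` returns `path`
#'   invisibly.
#' @export
write_asc <- function(g, path, digits = 15) {
  v <- g$values
  v[is.na(v)] <- -9999
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.6f", g$xmin),
    sprintf("yllcorner %.6f", g$ymin),
    sprintf("cellsize %.6f", g$cell),
    "NODATA_value -9999"), con)
  # ASCII grid rows run north -> south
  for (i in rev(seq_len(nrow(v))))
    writeLines(paste(formatC(v[i, ], digits = digits, format = "g"),
                     collapse = " "), con)
  invisible(path)
}

#' @rdname write_asc
#' @export
read_asc <- function(path, levels = NULL) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(hdr, "\\s+")
  key <- tolower(vapply(kv, `[`, "", 1))
  val <- as.numeric(vapply(kv, `[`, "", 2))
  names(val) <- key
  body <- scan(path, skip = 6, quiet = TRUE)
  nr <- val[["nrows"]]; nc <- val[["ncols"]]
  m <- matrix(body, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE]  # back to south-first rows
  m[m == val[["nodata_value"]]] <- NA
  sgrid(m, xmin = val[["xllcorner"]], ymin = val[["yllcorner"]],
        cell = val[["cellsize"]], levels = levels)
}
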