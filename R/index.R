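#' Min-max normalization parameters for a level surface
#'
#' Sound levels (dBA) and presence proportions live on different scales;
#' before aggregation the levels are rescaled to `[0, 1]` by subtracting
#' the data minimum and dividing by the data range. Parameters are fitted
#' over unmasked cells only and travel with the output, because a min-max
#' scheme is city-specific and hinders comparison across cities unless the
#' parameters are known.
#'
#' @param level an [sgrid] of levels (dBA) or a numeric vector.
#' @param mask optional logical vector/matrix, `TRUE` = masked (excluded
#'   from fitting).
#' @param period optional period label stored with the parameters.
#' @return List of class `norm_params` with `data_min`, `data_range` and
#'   `period`.
#' @export
normalization_params <- function(level, mask = NULL, period = NULL) {
  v <- if (inherits(level, "sgrid")) as.vector(level$values) else
    as.numeric(level)
  if (!is.null(mask)) v <- v[!as.vector(mask)]
  v <- v[!is.na(v)]
  rng <- max(v) - min(v)
  if (rng <= 0) stop("level surface has zero range; cannot normalize")
  structure(list(data_min = min(v), data_range = rng, period = period),
            class = "norm_params")
}

#' Normalize sound levels to the unit interval
#'
#' `(x - data_min) / data_range`. Equals 0 at the minimum and 1 at the
#' maximum of the fitting domain; values outside the fitting domain are
#' clamped into `[0, 1]` so the index stays bounded.
#'
#' @param level an [sgrid] or numeric vector of levels (dBA).
#' @param params a [normalization_params()] object.
#' @return Same shape as the input, normalized.
#' @export
normalize_levels <- function(level, params) {
  if (params$data_range <= 0) stop("data_range must be positive")
  f <- function(v) pmin(pmax((v - params$data_min) / params$data_range,
                             0), 1)
  if (inherits(level, "sgrid")) {
    level$values <- f(level$values)
    level
  } else f(as.numeric(level))
}

#' Convert prevalence percentages to proportions
#'
#' @param prevalence numeric in `[0, 100]` (percent).
#' @return `prevalence / 100`, in `[0, 1]`; out-of-range input errors.
#' @export
prevalence_to_proportion <- function(prevalence) {
  bad <- !is.na(prevalence) & (prevalence < 0 | prevalence > 100)
  if (any(bad)) stop("prevalence must be within [0, 100]")
  prevalence / 100
}

#' Weighted geometric aggregation of level and presence
#'
#' The SoundType Index cell value:
#' `norm_level^w_level * proportion^w_prevalence`, with equal weights the
#' geometric mean `sqrt(norm_level * proportion)`. Geometric aggregation
#' means either input at 0 annihilates the index (a silent-by-level or
#' never-present cell scores 0), and the result never exceeds the
#' arithmetic mean of its inputs.
#'
#' @param norm_level normalized levels in `[0, 1]`.
#' @param proportion presence proportions in `[0, 1]`.
#' @param weights numeric `(w_level, w_prevalence)`, non-negative and
#'   summing to 1.
#' @return Index values in `[0, 1]`.
#' @export
geometric_index <- function(norm_level, proportion,
                            weights = c(0.5, 0.5)) {
  if (length(weights) != 2 || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    stop("weights must be two non-negative values summing to 1")
  ok <- function(v) all(is.na(v) | (v >= 0 & v <= 1))
  if (!ok(norm_level) || !ok(proportion))
    stop("inputs to the geometric index must be in [0, 1]")
  norm_level^weights[1] * proportion^weights[2]
}

#' Build a SoundType Index surface
#'
#' Combines a sound-level surface with a prevalence surface of the same
#' period into a per-cell composite in `[0, 1]`: levels are min-max
#' normalized (per period, over unmasked cells), prevalences converted to
#' proportions, and the two aggregated geometrically with the given
#' weights. The output mask is the intersection of unmasked cells.
#'
#' @param level an [sgrid] of `L_day` or `L_night` (dBA) on the same grid
#'   as the prevalence surface.
#' @param prevalence_surface a [predict_surface()] surface (values in
#'   percent).
#' @param weights `(w_level, w_prevalence)`, default equal.
#' @param params optional pre-fitted [normalization_params()]; fitted on
#'   this surface's unmasked cells when `NULL`.
#' @return Object of class `surface` (and `index_surface`) with index
#'   values; the normalization parameters and weights are attached.
#' @export
build_index_surface <- function(level, prevalence_surface,
                                weights = c(0.5, 0.5), params = NULL) {
  g <- prevalence_surface$grid
  lv <- as.vector(level$values)
  if (length(lv) != length(prevalence_surface$values) ||
      !isTRUE(all.equal(level$cell, attr(g, "cell"))))
    stop("level and prevalence surfaces are on different grids")
  masked <- is.na(prevalence_surface$values)
  if (is.null(params))
    params <- normalization_params(lv, mask = masked,
                                   period = prevalence_surface$period)
  norm <- normalize_levels(lv, params)
  prop <- prevalence_to_proportion(prevalence_surface$values)
  values <- rep(NA_real_, length(lv))
  values[!masked] <- geometric_index(norm[!masked], prop[!masked], weights)
  structure(list(category = prevalence_surface$category,
                 period = prevalence_surface$period,
                 values = values, grid = g, params = params,
                 weights = weights,
                 reliable = prevalence_surface$reliable),
            class = c("index_surface", "surface"))
}
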