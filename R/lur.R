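#' Seeded regression random forest
#'
#' Bootstrap-aggregated CART regression trees with a random feature subset
#' at every split, the estimator behind the land-use-regression models.
#' Implemented in compiled code with in-bag bookkeeping so out-of-bag
#' predictions (the basis of permutation importance) are available without
#' refitting. Draws from R's RNG: the same seed, data and parameters give
#' identical forests.
#'
#' @param x numeric matrix or data.frame of predictors.
#' @param y numeric response.
#' @param n_trees number of trees (default 500).
#' @param mtry features tried per split; default `max(floor(p/3), 1)`, the
#'   regression-forest convention.
#' @param min_node node size below which splitting stops (default 5).
#' @param seed integer seed.
#' @return Object of class `rf_model`. Predictions are averages of leaf
#'   means, hence always within `[min(y), max(y)]`.
#' @export
rf_regression <- function(x, y, n_trees = 500,
                          mtry = max(floor(ncol(x) / 3), 1),
                          min_node = 5, seed = 1L) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (length(unique(y)) < 2)
    warning("degenerate fit: fewer than 2 distinct response values")
  set.seed(seed)
  forest <- cpp_rf_fit(x, as.numeric(y), as.integer(n_trees),
                       as.integer(mtry), as.integer(min_node))
  structure(list(forest = forest, features = colnames(x),
                 x = x, y = as.numeric(y),
                 y_range = range(y), n_trees = n_trees, mtry = mtry,
                 min_node = min_node, seed = seed),
            class = "rf_model")
}

#' @export
predict.rf_model <- function(object, newdata, ...) {
  nd <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  storage.mode(nd) <- "double"
  cpp_rf_predict(object$forest, nd)
}

# out-of-bag predictions on the training rows (NA for rows in-bag in
# every tree); x_override substitutes permuted columns
rf_oob_predict <- function(model, x_override = NULL) {
  x <- if (is.null(x_override)) model$x else x_override
  cpp_rf_predict_oob(model$forest, x)
}

#' A-priori period filter for predictor specs
#'
#' Drops predictors considered not sound-producing in the given period
#' (e.g. schools are excluded from night-time models).
#'
#' @param specs a [default_predictor_specs()]-style table with a `period`
#'   column in `{day, night, both}`.
#' @param period the model period, `"day"` or `"night"`.
#' @return The filtered spec table; error if nothing remains.
#' @export
apriori_filter <- function(specs, period) {
  stopifnot(period %in% c("day", "night"))
  out <- specs[specs$period %in% c("both", period), , drop = FALSE]
  if (nrow(out) == 0)
    stop(sprintf("no candidate predictors applicable to the %s period",
                 period))
  out
}

#' LUR model specification
#'
#' @param category sound-type category modeled.
#' @param period `"day"` or `"night"`.
#' @param n_trees forest size (default 500).
#' @param cv_folds site-grouped cross-validation folds (default 10).
#' @param n_perm permutations per variable for importance (default 10).
#' @param seed integer seed governing forest fitting, permutation draws and
#'   fold assignment.
#' @return List of class `lur_spec`.
#' @export
lur_spec <- function(category, period, n_trees = 500, cv_folds = 10,
                     n_perm = 10, seed = 1L) {
  stopifnot(n_trees >= 1, period %in% c("day", "night"))
  structure(list(category = category, period = period,
                 n_trees = as.integer(n_trees),
                 cv_folds = as.integer(cv_folds),
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "lur_spec")
}

# training rows for one category x period: response + predictor matrix
training_frame <- function(table, features, spec, columns) {
  dt <- as.data.table(table)[category == spec$category &
                               period == spec$period]
  if (nrow(dt) == 0)
    stop(sprintf("no training rows for %s/%s", spec$category, spec$period))
  fm <- as.data.frame(features)
  miss <- setdiff(columns, names(fm))
  if (length(miss))
    stop("feature matrix is missing columns: ", paste(miss, collapse = ", "))
  idx <- match(dt$site_id, fm$site_id)
  if (anyNA(idx)) stop("training sites missing from the feature matrix")
  list(y = dt$prevalence, x = as.matrix(fm[idx, columns, drop = FALSE]),
       site_id = dt$site_id, date = dt$date)
}

#' Permutation importance of forest predictors
#'
#' For each variable, the mean increase in out-of-bag MAE when the
#' variable's values are randomly permuted (breaking its association with
#' the response while keeping its marginal distribution), averaged over
#' `n_perm` seeded permutations. Important predictors produce a larger
#' accuracy drop when permuted.
#'
#' @param model an [rf_regression()] fit (or the `model` element of a
#'   [fit_lur()] object).
#' @param n_perm permutations per variable.
#' @param seed integer seed for the permutation draws.
#' @return data.frame `variable, importance` sorted by decreasing
#'   importance (MAE increase, percentage points).
#' @export
permutation_importance <- function(model, n_perm = 10, seed = 1L) {
  if (inherits(model, "fitted_lur")) model <- model$model
  oob <- rf_oob_predict(model)
  ok <- !is.na(oob)
  base_mae <- mean(abs(oob[ok] - model$y[ok]))
  set.seed(seed)
  p <- ncol(model$x)
  imp <- numeric(p)
  n <- nrow(model$x)
  for (j in seq_len(p)) {
    delta <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      xp <- model$x
      xp[, j] <- xp[sample(n), j]
      oobp <- rf_oob_predict(model, xp)
      okp <- !is.na(oobp)
      delta[b] <- mean(abs(oobp[okp] - model$y[okp])) - base_mae
    }
    imp[j] <- mean(delta)
  }
  out <- data.frame(variable = model$features, importance = imp,
                    stringsAsFactors = FALSE)
  out[order(-out$importance), , drop = FALSE]
}

#' Select the best buffer radius per predictor
#'
#' Fits one forest containing every candidate (variable, radius) column
#' simultaneously, computes permutation importance, and for each
#' multi-radius variable retains the radius with the largest mean
#' importance (ties broken toward the smaller, more local radius).
#' Unbuffered predictors pass through unchanged.
#'
#' @param table a [model_table()].
#' @param features site [build_feature_matrix()].
#' @param spec a [lur_spec()].
#' @return List of class `buffer_selection` with `columns` (retained
#'   feature columns), `choice` (data.frame `variable, radius`), and the
#'   full per-column `importance` table.
#' @export
select_buffer_radii <- function(table, features, spec) {
  specs <- apriori_filter(attr(features, "specs"), spec$period)
  candidate_cols <- unlist(lapply(seq_len(nrow(specs)), function(i)
    spec_columns(specs[i, ])))
  tf <- training_frame(table, features, spec, candidate_cols)
  model <- rf_regression(tf$x, tf$y, n_trees = spec$n_trees,
                         seed = spec$seed)
  imp <- permutation_importance(model, n_perm = spec$n_perm,
                                seed = spec$seed)
  base <- sub("@.*$", "", imp$variable)
  radius <- suppressWarnings(as.numeric(sub("^.*@", "", imp$variable)))
  keep <- character(0)
  choice <- list()
  for (v in unique(base)) {
    rows <- which(base == v)
    if (length(rows) == 1 && is.na(radius[rows])) {
      keep <- c(keep, imp$variable[rows])
      next
    }
    # max importance; ties toward the smaller radius
    o <- rows[order(-imp$importance[rows], radius[rows])][1]
    keep <- c(keep, imp$variable[o])
    choice[[length(choice) + 1]] <-
      data.frame(variable = v, radius = radius[o],
                 importance = imp$importance[o], stringsAsFactors = FALSE)
  }
  # deterministic column order: follow the spec expansion order
  keep <- candidate_cols[candidate_cols %in% keep]
  structure(list(columns = keep,
                 choice = do.call(rbind, choice),
                 importance = imp), class = "buffer_selection")
}

#' Fit a random forest LUR model
#'
#' Fits the 500-tree regression forest for one category and period on the
#' selected buffer columns. Models whose training response is more than
#' 80% zeros (in this analysis, geophysical nature sounds) are flagged
#' `reliable = FALSE`: such a forest cannot generalize above 0% and its
#' surfaces should not be reported.
#'
#' @param table a [model_table()].
#' @param features site [build_feature_matrix()].
#' @param spec a [lur_spec()].
#' @param selection a [select_buffer_radii()] result; computed if `NULL`.
#' @return Object of class `fitted_lur`: `spec`, `selection`, the
#'   `rf_model`, training bookkeeping and the reliability flag.
#' @export
fit_lur <- function(table, features, spec, selection = NULL) {
  if (is.null(selection)) selection <- select_buffer_radii(table, features,
                                                           spec)
  tf <- training_frame(table, features, spec, selection$columns)
  model <- rf_regression(tf$x, tf$y, n_trees = spec$n_trees,
                         seed = spec$seed)
  reliable <- mean(tf$y == 0) <= 0.8
  if (!reliable)
    warning(sprintf(
      "%s/%s: >80%% of training rows are 0%%; model flagged unreliable",
      spec$category, spec$period))
  structure(list(spec = spec, selection = selection, model = model,
                 train = data.frame(site_id = tf$site_id, date = tf$date,
                                    observed = tf$y,
                                    stringsAsFactors = FALSE),
                 reliable = reliable), class = "fitted_lur")
}

#' @export
print.fitted_lur <- function(x, ...) {
  cat(sprintf("<fitted_lur> %s / %s: %d trees, %d rows, %d predictors%s\n",
              x$spec$category, x$spec$period, x$spec$n_trees,
              nrow(x$train), length(x$selection$columns),
              if (x$reliable) "" else " [flagged unreliable]"))
  invisible(x)
}

#' @export
predict.fitted_lur <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)
  miss <- setdiff(object$model$features, names(nd))
  if (length(miss))
    stop("prediction data is missing columns: ",
         paste(miss, collapse = ", "))
  predict(object$model, nd)
}

#' Prediction accuracy metrics
#'
#' Mean error (bias), mean absolute error and median absolute error
#' (deviation), and the Pearson correlation of observed and predicted
#' values. All errors are `predicted - observed`, in the response's units
#' (percentage points here). A zero-variance vector makes `r` undefined;
#' it is returned as `NA` and flagged.
#'
#' @param observed,predicted equal-length numeric vectors, `n >= 2`.
#' @return List with `me, mae, mdae, r, r_defined, n`.
#' @export
cv_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  res <- predicted - observed
  r_def <- sd(observed) > 0 && sd(predicted) > 0
  list(me = mean(res), mae = mean(abs(res)), mdae = median(abs(res)),
       r = if (r_def) cor(observed, predicted) else NA_real_,
       r_defined = r_def, n = length(observed))
}

#' Site-grouped 10-fold cross-validation
#'
#' Sites are partitioned into `cv_folds` disjoint folds of ~10% of sites
#' each (seeded); all rows of a held-out site leave the training data
#' together, so the evaluation measures prediction at genuinely unmeasured
#' locations. Metrics are reported per fold and pooled over all held-out
#' predictions. Buffer selection is performed once on the full table and
#' held fixed across folds.
#'
#' @inheritParams fit_lur
#' @return Object of class `cv_report`: `pooled` metrics, `per_fold`
#'   data.frame, `predictions` (site_id, date, fold, observed, predicted),
#'   and the fold assignment.
#' @export
site_grouped_cv <- function(table, features, spec, selection = NULL) {
  if (is.null(selection)) selection <- select_buffer_radii(table, features,
                                                           spec)
  dt <- as.data.table(table)[category == spec$category &
                               period == spec$period]
  sites <- sort(unique(dt$site_id))
  if (length(sites) < spec$cv_folds)
    stop(sprintf("need at least %d distinct sites for %d-fold CV",
                 spec$cv_folds, spec$cv_folds))
  set.seed(derive_seed(spec$seed, 91))
  fold <- setNames(sample(rep(seq_len(spec$cv_folds),
                              length.out = length(sites))), sites)
  preds <- vector("list", spec$cv_folds)
  per_fold <- vector("list", spec$cv_folds)
  for (f in seq_len(spec$cv_folds)) {
    hold <- names(fold)[fold == f]
    train_tab <- dt[!site_id %in% hold]
    tf <- training_frame(train_tab, features, spec, selection$columns)
    model <- rf_regression(tf$x, tf$y, n_trees = spec$n_trees,
                           seed = derive_seed(spec$seed, 100 + f))
    test <- dt[site_id %in% hold]
    fm <- as.data.frame(features)
    xt <- fm[match(test$site_id, fm$site_id), selection$columns,
             drop = FALSE]
    pr <- predict(model, xt)
    preds[[f]] <- data.frame(site_id = test$site_id, date = test$date,
                             fold = f, observed = test$prevalence,
                             predicted = pr, stringsAsFactors = FALSE)
    m <- cv_metrics(test$prevalence, pr)
    per_fold[[f]] <- data.frame(fold = f, n = m$n, me = m$me, mae = m$mae,
                                mdae = m$mdae, r = m$r)
  }
  preds <- do.call(rbind, preds)
  structure(list(
    pooled = cv_metrics(preds$observed, preds$predicted),
    per_fold = do.call(rbind, per_fold),
    predictions = preds, fold = fold, spec = spec), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  p <- x$pooled
  cat(sprintf(
    "<cv_report> %s / %s: pooled MdAE %.2f, MAE %.2f, ME %.2f, r %.3f (n=%d)\n",
    x$spec$category, x$spec$period, p$mdae, p$mae, p$me,
    ifelse(is.na(p$r), NaN, p$r), p$n))
  invisible(x)
}

# spatial weight matrix for Moran's I; diag 0, row-standardized
moran_weights <- function(coords, scheme = c("idw", "knn", "band"),
                          k = 5, band = NULL) {
  scheme <- match.arg(scheme)
  d <- as.matrix(stats::dist(coords))
  n <- nrow(d)
  w <- switch(scheme,
    idw = {
      dd <- d; diag(dd) <- Inf
      1 / dd
    },
    knn = {
      w <- matrix(0, n, n)
      for (i in seq_len(n)) {
        nb <- order(d[i, -i])[seq_len(min(k, n - 1))]
        w[i, setdiff(seq_len(n), i)[nb]] <- 1
      }
      w
    },
    band = {
      if (is.null(band)) stop("band scheme needs a distance band")
      w <- (d <= band) * 1
      diag(w) <- 0
      w
    })
  rs <- rowSums(w)
  rs[rs == 0] <- 1
  w / rs
}

#' Moran's I test of spatial autocorrelation
#'
#' Global Moran's I on model residuals:
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centered
#' residuals. Under no spatial autocorrelation `E[I] = -1/(n-1)`; the test
#' uses the normality-assumption variance and a two-sided normal p-value.
#' Default weights are row-standardized inverse distance with no cutoff;
#' k-nearest-neighbour and distance-band schemes are available.
#'
#' @param residuals numeric residual vector (one per site).
#' @param coords two-column matrix/data.frame of site coordinates (m).
#' @param scheme `"idw"`, `"knn"` or `"band"`.
#' @param k neighbours for `"knn"`.
#' @param band distance cutoff in meters for `"band"`.
#' @return List of class `morans_i`: `I, expectation, variance, z,
#'   p_value, n, scheme`.
#' @export
morans_i <- function(residuals, coords, scheme = "idw", k = 5,
                     band = NULL) {
  n <- length(residuals)
  if (n < 3) stop("Moran's I needs at least 3 sites")
  if (sd(residuals) == 0) stop("residuals have zero variance")
  coords <- as.matrix(as.data.frame(coords)[, c("x", "y")])
  stopifnot(nrow(coords) == n)
  w <- moran_weights(coords, scheme = scheme, k = k, band = band)
  z <- residuals - mean(residuals)
  s0 <- sum(w)
  i_stat <- (n / s0) * as.numeric(t(z) %*% w %*% z) / sum(z^2)
  e_i <- -1 / (n - 1)
  s1 <- 0.5 * sum((w + t(w))^2)
  s2 <- sum((rowSums(w) + colSums(w))^2)
  var_i <- (n^2 * s1 - n * s2 + 3 * s0^2) / ((n^2 - 1) * s0^2) - e_i^2
  zscore <- (i_stat - e_i) / sqrt(var_i)
  structure(list(I = i_stat, expectation = e_i, variance = var_i,
                 z = zscore, p_value = 2 * pnorm(-abs(zscore)), n = n,
                 scheme = scheme), class = "morans_i")
}

#' @export
print.morans_i <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f, z = %.2f, p = %.4g, n = %d)\n",
              x$I, x$expectation, x$z, x$p_value, x$n))
  invisible(x)
}

#' Combined standardized residual score across models
#'
#' Takes per-site absolute residuals from several models of the same
#' period, min-max scales each model's values to `[0, 1]`, and sums them
#' per site. High scores mark sites that are poorly predicted by many
#' sound-type models at once. A model with constant absolute residuals has
#' zero range; its scaled values are set to 0 with a warning.
#'
#' @param residuals matrix or data.frame of residuals, rows = sites,
#'   columns = models (site alignment is the caller's responsibility).
#' @return Numeric vector of per-site scores in `[0, n_models]`.
#' @export
combined_residual_score <- function(residuals) {
  m <- abs(as.matrix(residuals))
  if (ncol(m) < 2) stop("need residuals from at least 2 models")
  scaled <- apply(m, 2, function(v) {
    rng <- max(v) - min(v)
    if (rng == 0) {
      warning("model with constant |residuals|; scaled values set to 0")
      rep(0, length(v))
    } else (v - min(v)) / rng
  })
  rowSums(scaled)
}

#' Residual summaries over time groupings
#'
#' Descriptive inspection of residual distributions across time intervals
#' (e.g. day of week, month): mean, median and SD per group.
#'
#' @param predictions a `cv_report$predictions` data.frame (needs `date`,
#'   `observed`, `predicted`).
#' @param by `"weekday"` or `"month"`.
#' @return data.frame of per-group residual summaries.
#' @export
residual_time_summary <- function(predictions, by = c("weekday", "month")) {
  by <- match.arg(by)
  g <- if (by == "weekday") weekdays(as.Date(predictions$date))
       else months(as.Date(predictions$date))
  res <- predictions$predicted - predictions$observed
  out <- aggregate(data.frame(mean_error = res, abs_error = abs(res)),
                   by = list(group = g),
                   FUN = mean)
  out$median_abs_error <- tapply(abs(res), g, median)[out$group]
  out
}
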