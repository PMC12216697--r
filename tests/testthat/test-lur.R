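test_that("a-priori filter removes period-inapplicable predictors", {
  specs <- default_predictor_specs()
  night <- apriori_filter(specs, "night")
  expect_false("poi_school" %in% night$name)
  day <- apriori_filter(specs, "day")
  expect_true("poi_school" %in% day$name)
  expect_true(all(c("road_major", "ndvi") %in% night$name))
  day_only <- specs[specs$period == "day", ]
  expect_error(apriori_filter(day_only, "night"), "night")
})

test_that("cv_metrics matches hand arithmetic and flags undefined r", {
  m <- cv_metrics(c(0, 0, 0), c(1, -1, 3))
  expect_equal(m$me, 1.0)
  expect_equal(m$mae, 5 / 3)
  expect_equal(m$mdae, 1.0)
  expect_equal(cv_metrics(c(0, 10, 20), c(0, 10, 20))$r, 1.0)
  perfect_const <- cv_metrics(c(5, 5, 5), c(5, 5, 5))
  expect_equal(perfect_const$mae, 0)
  expect_true(is.na(perfect_const$r))
  expect_false(perfect_const$r_defined)
})

test_that("site-grouped folds are disjoint, covering, and order-stable", {
  a <- small_artifacts()
  spec <- lur_spec("road_transport", "day", n_trees = 40, cv_folds = 5,
                   n_perm = 2, seed = 3)
  sel <- select_buffer_radii(a$table, a$features, spec)
  cv <- site_grouped_cv(a$table, a$features, spec, sel)
  folds <- cv$fold
  expect_setequal(names(folds),
                  unique(a$table[a$table$period == "day" &
                                   a$table$category == "road_transport",
                                 ]$site_id))
  expect_equal(sort(unique(unname(folds))), 1:5)
  # no leak: every held-out prediction comes from the site's own fold
  pred_folds <- tapply(cv$predictions$fold, cv$predictions$site_id,
                       function(v) length(unique(v)))
  expect_true(all(pred_folds == 1))
  # shuffling row order does not change fold membership
  set.seed(9)
  shuffled <- a$table[sample(nrow(a$table)), ]
  cv2 <- site_grouped_cv(shuffled, a$features, spec, sel)
  expect_identical(cv$fold, cv2$fold)
  # too few sites errors
  tiny <- a$table[a$table$site_id %in% names(folds)[1:3], ]
  expect_error(site_grouped_cv(tiny, a$features, spec, sel), "folds|sites")
})

test_that("permutation importance ranks the sole signal first", {
  set.seed(21)
  n <- 150
  x <- matrix(runif(n * 5), n, 5,
              dimnames = list(NULL, c("signal", paste0("noise", 1:4))))
  y <- 60 * x[, "signal"] + rnorm(n, sd = 3)
  fit <- rf_regression(x, y, n_trees = 150, seed = 2)
  imp <- permutation_importance(fit, n_perm = 10, seed = 4)
  expect_equal(imp$variable[1], "signal")
  expect_gt(imp$importance[1], 5 * max(abs(imp$importance[-1])))

  # duplicating a noise column leaves the signal on top
  x2 <- cbind(x, noise_dup = x[, "noise1"])
  fit2 <- rf_regression(x2, y, n_trees = 150, seed = 2)
  imp2 <- permutation_importance(fit2, n_perm = 10, seed = 4)
  expect_equal(imp2$variable[1], "signal")

  # seeded determinism
  imp3 <- permutation_importance(fit, n_perm = 10, seed = 4)
  expect_identical(imp, imp3)
})

test_that("pure-noise importances are indistinguishable from zero", {
  set.seed(33)
  n <- 120
  x <- matrix(runif(n * 6), n, 6,
              dimnames = list(NULL, paste0("n", 1:6)))
  y <- rnorm(n)
  fit <- rf_regression(x, y, n_trees = 150, seed = 5)
  imp <- permutation_importance(fit, n_perm = 10, seed = 6)
  # sign test: noise importances scatter around 0, not systematically +
  expect_gte(sum(imp$importance < 0), 1)
  expect_lt(max(abs(imp$importance)), sd(y))
})

test_that("buffer selection retains one radius per variable, seeded", {
  a <- small_artifacts()
  spec <- lur_spec("road_transport", "day", n_trees = 60, n_perm = 3,
                   seed = 8)
  sel <- select_buffer_radii(a$table, a$features, spec)
  base <- sub("@.*$", "", sel$columns)
  expect_false(any(duplicated(base)))
  multi <- unique(sub("@.*$", "",
                      grep("@", names(a$features), value = TRUE)))
  expect_setequal(sel$choice$variable, multi)
  expect_true(all(sel$choice$radius %in% c(50, 100, 200, 500)))
  sel2 <- select_buffer_radii(a$table, a$features, spec)
  expect_identical(sel$columns, sel2$columns)
})

test_that("fit_lur predicts within the training range and flags skew", {
  a <- small_artifacts()
  spec <- lur_spec("road_transport", "day", n_trees = 60, n_perm = 3,
                   seed = 8)
  fit <- fit_lur(a$table, a$features, spec)
  p <- predict(fit, a$features)
  expect_true(all(p >= min(fit$train$observed) &
                    p <= max(fit$train$observed)))
  # >80% zero response -> unreliable flag
  tab0 <- a$table[a$table$category == "road_transport" &
                    a$table$period == "day", ]
  tab0$prevalence <- ifelse(seq_len(nrow(tab0)) %% 10 == 0, 5, 0)
  expect_warning(fit0 <- fit_lur(tab0, a$features, spec,
                                 fit$selection), "unreliable")
  expect_false(fit0$reliable)
  # missing prediction columns are named
  expect_error(predict(fit, a$features[, 1:3]), "missing columns")
})

test_that("Moran's I matches hand-evaluated cases", {
  # E[I] = -1/(n-1)
  set.seed(2)
  m5 <- morans_i(rnorm(5), data.frame(x = runif(5), y = runif(5)))
  expect_equal(m5$expectation, -0.25)
  # 2x2 rook lattice with a +1/-1 checkerboard: I = -1 exactly
  coords <- data.frame(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  res <- c(1, -1, -1, 1)
  m <- morans_i(res, coords, scheme = "band", band = 1)
  expect_equal(m$I, -1)
  # two tight clusters with opposite-sign residuals: strong positive I
  cl <- rbind(cbind(rnorm(10, 0, 1), rnorm(10, 0, 1)),
              cbind(rnorm(10, 1000, 1), rnorm(10, 1000, 1)))
  r2 <- c(rnorm(10, 5, 0.1), rnorm(10, -5, 0.1))
  m2 <- morans_i(r2, data.frame(x = cl[, 1], y = cl[, 2]))
  expect_gt(m2$I, 0.5)
  expect_lt(m2$p_value, 0.01)
  # degenerate inputs
  expect_error(morans_i(c(1, 1, 1), data.frame(x = 1:3, y = 1:3)),
               "variance")
  expect_error(morans_i(c(1, 2), data.frame(x = 1:2, y = 1:2)), "3")
})

test_that("Moran's I brute-force formula agreement on random data", {
  set.seed(14)
  n <- 25
  coords <- data.frame(x = runif(n, 0, 1000), y = runif(n, 0, 1000))
  res <- rnorm(n)
  m <- morans_i(res, coords)
  # independent evaluation of I = (n/S0) sum wij zi zj / sum zi^2
  d <- as.matrix(dist(coords)); diag(d) <- Inf
  w <- 1 / d; w <- w / rowSums(w)
  z <- res - mean(res)
  i_brute <- (n / sum(w)) * sum(outer(z, z) * w) / sum(z^2)
  expect_equal(m$I, i_brute, tolerance = 1e-12)
})

test_that("combined residual score sums min-max scaled |residuals|", {
  res <- cbind(m1 = c(0.5, -1, 2), m2 = c(3, 0, -6))
  s <- combined_residual_score(res)
  # model 1: |res| = (.5, 1, 2) -> scaled (0, 1/3, 1); model 2 -> (.5, 0, 1)
  expect_equal(s, c(0.5, 1 / 3, 2))
  expect_true(all(s >= 0 & s <= 2))
  expect_error(combined_residual_score(res[, 1, drop = FALSE]), "2 models")
  expect_warning(combined_residual_score(cbind(c(1, 1, 1), c(0, 1, 2))),
                 "constant")
})
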