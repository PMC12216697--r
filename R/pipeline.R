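#' Validate a pipeline configuration
#'
#' Fills defaults (500 trees, 10 folds, radii {50, 100, 200, 500}, 50 m
#' cells, 30-day fixed-site subsample, equal index weights) and rejects
#' contradictions, reporting every violation at once: unknown keys, buffer
#' radii outside the allowed set, index weights not summing to 1.
#'
#' @param config a named list, typically parsed from YAML or JSON (see
#'   [read_pipeline_config()]).
#' @return Validated config of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  violations <- character(0)
  allowed_top <- c("seed", "out_dir", "city", "lur", "subsample_fixed_days",
                   "index_weights", "run_cv", "categories", "ontology")
  unknown <- setdiff(names(config), allowed_top)
  if (length(unknown))
    violations <- c(violations,
                    paste("unknown config keys:",
                          paste(unknown, collapse = ", ")))

  city_args <- config$city %||% list()
  known_city <- names(formals(city_config))
  unknown_city <- setdiff(names(city_args), known_city)
  if (length(unknown_city))
    violations <- c(violations,
                    paste("unknown city keys:",
                          paste(unknown_city, collapse = ", ")))

  lur <- config$lur %||% list()
  allowed_lur <- c("n_trees", "cv_folds", "n_perm", "radii")
  unknown_lur <- setdiff(names(lur), allowed_lur)
  if (length(unknown_lur))
    violations <- c(violations,
                    paste("unknown lur keys:",
                          paste(unknown_lur, collapse = ", ")))
  lur$n_trees <- lur$n_trees %||% 500L
  lur$cv_folds <- lur$cv_folds %||% 10L
  lur$n_perm <- lur$n_perm %||% 10L
  lur$radii <- sort(as.numeric(unlist(lur$radii %||% c(50, 100, 200, 500))))
  bad_radii <- setdiff(lur$radii, c(50, 100, 200, 500))
  if (length(bad_radii))
    violations <- c(violations,
                    paste("buffer radii outside {50, 100, 200, 500}:",
                          paste(bad_radii, collapse = ", ")))

  weights <- as.numeric(unlist(config$index_weights %||% c(0.5, 0.5)))
  if (length(weights) != 2 || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9)
    violations <- c(violations,
                    "index_weights must be two non-negative values summing to 1")

  if (length(violations))
    stop("invalid configuration:\n  - ",
         paste(violations, collapse = "\n  - "))

  seed <- as.integer(config$seed %||% 1L)
  city_args$seed <- city_args$seed %||% seed
  structure(list(
    seed = seed,
    out_dir = config$out_dir %||% "soundlur_run",
    city = do.call(city_config, city_args),
    lur = lur,
    subsample_fixed_days = as.integer(config$subsample_fixed_days %||% 30L),
    index_weights = weights,
    run_cv = isTRUE(config$run_cv %||% TRUE),
    categories = unlist(config$categories %||% modeled_categories()),
    ontology = config$ontology), class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration file
#'
#' YAML (`.yaml`/`.yml`, requires the yaml package) or JSON.
#'
#' @param path config file path.
#' @return Validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package; use JSON")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_config(cfg)
}

#' Read an ontology mapping file
#'
#' YAML or JSON object mapping fine class labels to categories.
#'
#' @param path mapping file.
#' @return A [sound_ontology()].
#' @export
read_ontology <- function(path) {
  m <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML ontologies requires the yaml package; use JSON")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  sound_ontology(unlist(m))
}

#' Run the full pipeline
#'
#' Executes simulate -> prevalence -> features -> fit (per category and
#' period) -> predict -> index, writing every stage's artifacts under
#' `out_dir` and a run manifest (seeds, per-stage wall time, md5 of every
#' output file). Any stage failure aborts with a stage-tagged error; prior
#' outputs are preserved. Re-running with the same config and seed
#' reproduces byte-identical outputs.
#'
#' Ten models are constructed by default (5 categories x 2 periods);
#' models flagged unreliable (response >80% zeros, here geophysical
#' nature) are fitted and reported in the manifest but their surfaces are
#' not written.
#'
#' @param config a `pipeline_config` (see [validate_config()]) or a plain
#'   list to validate.
#' @param out_dir output directory; overrides the config's.
#' @return Invisibly, a list with the manifest and all in-memory stage
#'   products (`city`, `table`, `features`, `fits`, `cv`, `surfaces`,
#'   `index_surfaces`, `diagnostics`).
#' @export
run_all <- function(config = list(), out_dir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(seed = cfg$seed, stages = list())
  run_stage <- function(name, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    files <- res$files %||% character(0)
    hashes <- if (length(files))
      as.list(tools::md5sum(file.path(out_dir, files))) else list()
    names(hashes) <- files
    manifest$stages[[name]] <<- list(
      name = name, elapsed_s = round(proc.time()[["elapsed"]] - t0, 3),
      outputs = hashes)
    res$value
  }

  ontology <- if (is.null(cfg$ontology)) default_ontology()
              else read_ontology(cfg$ontology)

  city <- run_stage("simulate", function() {
    city <- simulate_city(cfg$city, ontology)
    write_layers(city$rasters, city$vectors, file.path(out_dir, "layers"))
    write_sites_csv(city$sites, file.path(out_dir, "sites.csv"))
    write_clips_csv(city$clips, file.path(out_dir, "clips.csv"))
    write_asc(city$levels$L_day, file.path(out_dir, "L_day.asc"))
    write_asc(city$levels$L_night, file.path(out_dir, "L_night.asc"))
    list(value = city,
         files = c(file.path("layers", c(
           "ndvi.asc", "pop_density.asc", "land_cover.asc",
           "elevation.asc", "water.asc", "roads.geojson", "pois.geojson",
           "waterways.geojson", "buildings.geojson")),
           "sites.csv", "clips.csv", "L_day.asc", "L_night.asc"))
  })

  table <- run_stage("prevalence", function() {
    prev <- compute_prevalence(city$clips, ontology)
    write_prevalence_csv(prev, file.path(out_dir, "prevalence.csv"))
    tab <- model_table(prev, city$sites)
    tab <- subsample_fixed_site_days(tab, cfg$subsample_fixed_days,
                                     seed = derive_seed(cfg$seed, 20))
    fwrite(tab, file.path(out_dir, "model_table.csv"))
    list(value = tab, files = c("prevalence.csv", "model_table.csv"))
  })

  feats <- run_stage("features", function() {
    specs <- default_predictor_specs(radii = cfg$lur$radii)
    layers <- list(rasters = city$rasters, vectors = city$vectors)
    site_fm <- build_feature_matrix(city$sites, layers, specs)
    write_feature_matrix(site_fm, file.path(out_dir, "features_sites.csv"))
    grid <- build_grid(cfg$city$extent_m, cfg$city$cell_size_m)
    grid <- compute_mask(grid, layers)
    grid_fm <- build_feature_matrix(grid, layers, specs)
    write_feature_matrix(grid_fm, file.path(out_dir, "features_grid.csv"))
    mask_code <- grid$no_roads + 2L * grid$water + 4L * grid$natural_only
    write_asc(sgrid(matrix(mask_code, nrow = attr(grid, "nrow")),
                    cell = attr(grid, "cell")),
              file.path(out_dir, "mask.asc"))
    list(value = list(sites = site_fm, grid_fm = grid_fm, grid = grid,
                      specs = specs),
         files = c("features_sites.csv", "features_sites.csv.json",
                   "features_grid.csv", "features_grid.csv.json",
                   "mask.asc"))
  })

  models <- run_stage("fit", function() {
    fits <- list(); cvs <- list(); files <- character(0)
    dir.create(file.path(out_dir, "models"), showWarnings = FALSE)
    for (cat in cfg$categories) for (per in c("day", "night")) {
      key <- paste(cat, per, sep = "_")
      spec <- lur_spec(cat, per, n_trees = cfg$lur$n_trees,
                       cv_folds = cfg$lur$cv_folds,
                       n_perm = cfg$lur$n_perm,
                       seed = derive_seed(cfg$seed, 30))
      sel <- select_buffer_radii(table, feats$sites, spec)
      fit <- withCallingHandlers(
        fit_lur(table, feats$sites, spec, sel),
        warning = function(w) invokeRestart("muffleWarning"))
      fits[[key]] <- fit
      f <- file.path("models", paste0(key, ".json"))
      write_fitted_lur(fit, file.path(out_dir, f))
      files <- c(files, f)
      if (cfg$run_cv) {
        cvs[[key]] <- site_grouped_cv(table, feats$sites, spec, sel)
      }
    }
    if (cfg$run_cv) {
      cv_rows <- rbindlist(lapply(names(cvs), function(k) {
        p <- cvs[[k]]$pooled
        data.table(model = k, n = p$n, me = p$me, mae = p$mae,
                   mdae = p$mdae, r = p$r)
      }))
      fwrite(cv_rows, file.path(out_dir, "cv_report.csv"))
      files <- c(files, "cv_report.csv")
    }
    list(value = list(fits = fits, cvs = cvs), files = files)
  })

  diagnostics <- run_stage("diagnostics", function() {
    # per-site mean OOB residual per model; Moran's I; combined score
    site_xy <- city$sites[, c("site_id", "x", "y")]
    moran <- list(); per_site <- list()
    for (key in names(models$fits)) {
      fit <- models$fits[[key]]
      oob <- rf_oob_predict(fit$model)
      res <- oob - fit$model$y
      d <- data.table(site_id = fit$train$site_id, res = res)
      ms <- d[!is.na(res), .(me = mean(res)), by = site_id]
      per_site[[key]] <- ms
      m <- merge(ms, site_xy, by = "site_id")
      mi <- morans_i(m$me, m[, c("x", "y")])
      moran[[key]] <- list(I = mi$I, expectation = mi$expectation,
                           variance = mi$variance, z = mi$z,
                           p_value = mi$p_value, n = mi$n)
    }
    diag_rows <- list()
    for (per in c("day", "night")) {
      keys <- grep(paste0("_", per, "$"), names(per_site), value = TRUE)
      if (length(keys) < 2) next
      wide <- Reduce(function(a, b) merge(a, b, by = "site_id"),
                     lapply(keys, function(k)
                       setNames(per_site[[k]], c("site_id", k))))
      score <- combined_residual_score(as.matrix(wide[, -1,
                                                      with = FALSE]))
      diag_rows[[per]] <- data.table(
        site_id = wide$site_id, period = per,
        mean_error = rowMeans(as.matrix(wide[, -1, with = FALSE])),
        combined_score = score)
    }
    fwrite(rbindlist(diag_rows), file.path(out_dir, "diagnostics.csv"))
    jsonlite::write_json(moran, file.path(out_dir, "morans_i.json"),
                         auto_unbox = TRUE, digits = NA)
    list(value = list(moran = moran),
         files = c("diagnostics.csv", "morans_i.json"))
  })

  surfaces <- run_stage("predict", function() {
    dir.create(file.path(out_dir, "surfaces"), showWarnings = FALSE)
    surfs <- list(); files <- character(0); summ <- list()
    zones <- surface_zones(feats$grid, cfg$city, city$vectors)
    for (key in names(models$fits)) {
      fit <- models$fits[[key]]
      surf <- predict_surface(fit, feats$grid_fm, feats$grid)
      surfs[[key]] <- surf
      if (fit$reliable) {
        f <- file.path("surfaces", paste0(key, ".asc"))
        write_asc(surface_to_sgrid(surf), file.path(out_dir, f))
        files <- c(files, f)
        s <- summarize_surface(surf, zones)
        s$model <- key
        summ[[key]] <- s
      }
    }
    fwrite(rbindlist(summ), file.path(out_dir, "surface_summaries.csv"))
    list(value = surfs, files = c(files, "surface_summaries.csv"))
  })

  index_surfaces <- run_stage("index", function() {
    dir.create(file.path(out_dir, "index"), showWarnings = FALSE)
    isurfs <- list(); files <- character(0); params <- list()
    for (key in names(surfaces)) {
      surf <- surfaces[[key]]
      if (!isTRUE(surf$reliable)) next
      level <- if (surf$period == "day") city$levels$L_day
               else city$levels$L_night
      isurf <- build_index_surface(level, surf,
                                   weights = cfg$index_weights)
      isurfs[[key]] <- isurf
      f <- file.path("index", paste0(key, "_index.asc"))
      write_asc(surface_to_sgrid(isurf), file.path(out_dir, f))
      files <- c(files, f)
      params[[key]] <- list(data_min = isurf$params$data_min,
                            data_range = isurf$params$data_range,
                            weights = cfg$index_weights)
    }
    jsonlite::write_json(params, file.path(out_dir, "index",
                                           "index_params.json"),
                         auto_unbox = TRUE, digits = NA)
    list(value = isurfs,
         files = c(files, file.path("index", "index_params.json")))
  })

  manifest$package_version <-
    as.character(utils::packageVersion("soundlur"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, city = city, table = table,
                 features = feats, fits = models$fits, cv = models$cvs,
                 diagnostics = diagnostics, surfaces = surfaces,
                 index_surfaces = index_surfaces, out_dir = out_dir))
}

#' Manifest hash table of a finished run
#'
#' Convenience accessor for determinism checks: every output file's md5,
#' flattened to a named character vector (wall times excluded, since they
#' are not deterministic outputs).
#'
#' @param manifest a manifest list or a path to `manifest.json`.
#' @return Named character vector `file -> md5`.
#' @export
manifest_hashes <- function(manifest) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  out <- unlist(lapply(manifest$stages, function(s) s$outputs))
  vapply(out, as.character, "")
}
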