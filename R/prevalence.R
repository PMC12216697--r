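#' Sound-category ontology
#'
#' Total mapping from fine sound-class labels to the seven higher-order
#' sound-type categories used throughout: road_transport, animal_insect,
#' music, speech, aircraft, geophysical_nature and other. Any label absent
#' from the mapping falls into `other`. The fine vocabulary is a
#' configurable stand-in for whatever classifier produced the clips.
#'
#' @param map named character vector, `fine class -> category`.
#' @return List of class `ontology` with elements `map` and `categories`.
#' @export
sound_ontology <- function(map) {
  cats <- sound_categories()
  if (!all(map %in% cats))
    stop("unknown category in ontology: ",
         paste(setdiff(map, cats), collapse = ", "))
  structure(list(map = map, categories = cats), class = "ontology")
}

#' @rdname sound_ontology
#' @export
default_ontology <- function() {
  sound_ontology(c(
    vehicle_engine = "road_transport", honking = "road_transport",
    traffic_hum = "road_transport", motorcycle = "road_transport",
    birdsong = "animal_insect", insect_buzz = "animal_insect",
    dog_bark = "animal_insect", rooster = "animal_insect",
    radio_music = "music", singing = "music", drumming = "music",
    talking = "speech", laughter = "speech", shouting = "speech",
    airplane_flyover = "aircraft",
    rain = "geophysical_nature", wind = "geophysical_nature",
    thunder = "geophysical_nature",
    clatter = "other", alarm = "other", smash = "other"))
}

#' The seven sound-type categories
#'
#' @return Character vector of category names. `aircraft` and `other` are
#'   computed but excluded from modelling by default (see
#'   [modeled_categories()]).
#' @export
sound_categories <- function() {
  c("road_transport", "animal_insect", "music", "speech", "aircraft",
    "geophysical_nature", "other")
}

#' @rdname sound_categories
#' @export
modeled_categories <- function() {
  c("road_transport", "animal_insect", "music", "speech",
    "geophysical_nature")
}

#' Map one clip's detected classes to categories
#'
#' Unknown fine labels map to `other`, so the result is never empty for a
#' clip with at least one detected class. Detected categories can overlap
#' (sound types are not mutually exclusive), but a clip carries at most
#' three classes, hence at most three categories.
#'
#' @param clip character vector of 1-3 fine class labels (NAs ignored), or
#'   a one-row clip table with `class1..class3`.
#' @param ontology a [sound_ontology()].
#' @return Character vector: the set of categories present in the clip.
#' @export
map_clip_to_categories <- function(clip, ontology = default_ontology()) {
  if (is.list(clip) || is.data.frame(clip))
    clip <- unlist(clip[c("class1", "class2", "class3")], use.names = FALSE)
  clip <- clip[!is.na(clip)]
  if (length(clip) == 0) return(character(0))
  cats <- unname(ontology$map[clip])
  cats[is.na(cats)] <- "other"
  unique(cats)
}

#' Assign a timestamp to the day or night period
#'
#' Day is 06:00-21:59 (clock time in `[06:00, 22:00)`), night is
#' 22:00-05:59. A clip at exactly 22:00:00 is night; at exactly 06:00:00 it
#' is day.
#'
#' @param timestamp POSIXct vector, or character `"HH:MM"` /
#'   `"YYYY-MM-DD HH:MM"` strings.
#' @return Character vector, `"day"` or `"night"`.
#' @export
assign_period <- function(timestamp) {
  if (inherits(timestamp, "POSIXct")) {
    hour <- as.POSIXlt(timestamp)$hour
  } else {
    tm <- sub("^.*\\s", "", as.character(timestamp))
    hour <- as.integer(sub(":.*$", "", tm))
  }
  ifelse(hour >= 6 & hour < 22, "day", "night")
}

# date a period observation is attached to: a night is attached to the date
# on which it begins (22:00 of d .. 05:59 of d+1 = night of d)
period_date <- function(timestamp) {
  lt <- as.POSIXlt(timestamp)
  d <- as.Date(format(timestamp, "%Y-%m-%d"))
  d[lt$hour < 6] <- d[lt$hour < 6] - 1
  d
}

#' Compute sound-type prevalence per site, date and period
#'
#' Prevalence is the percentage of clips in a (site, date, period) cell in
#' which a category was detected: `100 * n_present / n_clips`. Every
#' category of the ontology gets a record in every retained cell, so
#' categories absent from all clips have prevalence 0. Cells with fewer
#' clips than `min_clip_fraction` of the full schedule (96 day clips, 48
#' night clips) are dropped: partial deployment days produce unstable
#' prevalences from a handful of clips.
#'
#' @param clips clip table (`site_id, timestamp, class1..class3`), e.g. from
#'   [simulate_clip_labels()] or [read_clips_csv()].
#' @param ontology a [sound_ontology()].
#' @param min_clip_fraction minimum observed fraction of the scheduled
#'   clips for a cell to be retained.
#' @return data.table with columns `site_id, date, period, category,
#'   n_clips, n_present, prevalence`.
#' @export
compute_prevalence <- function(clips, ontology = default_ontology(),
                               min_clip_fraction = 0.5) {
  clips <- as.data.table(clips)
  if (nrow(clips) == 0) {
    return(data.table(site_id = character(0), date = as.Date(character(0)),
                      period = character(0), category = character(0),
                      n_clips = integer(0), n_present = integer(0),
                      prevalence = numeric(0)))
  }
  cats <- ontology$categories
  map_col <- function(cl) {
    m <- unname(ontology$map[cl])
    m[is.na(m) & !is.na(cl)] <- "other"
    m
  }
  c1 <- map_col(clips$class1); c2 <- map_col(clips$class2)
  c3 <- map_col(clips$class3)
  pres <- as.data.table(lapply(setNames(cats, cats), function(cc) {
    (!is.na(c1) & c1 == cc) | (!is.na(c2) & c2 == cc) |
      (!is.na(c3) & c3 == cc)
  }))
  dt <- cbind(clips[, .(site_id)],
              date = period_date(clips$timestamp),
              period = assign_period(clips$timestamp), pres)
  agg <- dt[, c(list(n_clips = .N), lapply(.SD, sum)),
            by = .(site_id, date, period), .SDcols = cats]
  sched <- c(day = 96L, night = 48L)
  agg <- agg[n_clips >= min_clip_fraction * sched[period]]
  long <- melt(agg, id.vars = c("site_id", "date", "period", "n_clips"),
               variable.name = "category", value.name = "n_present",
               variable.factor = FALSE)
  long[, n_present := as.integer(n_present)]
  long[, prevalence := 100 * n_present / n_clips]
  setorder(long, site_id, date, period, category)
  long[]
}

#' Build the LUR model table
#'
#' Joins prevalence records to site metadata and restricts to the modelled
#' categories. Rows are site-date-period prevalences (not per-site means):
#' the 30-day fixed-site subsampling operates on dated rows, and prediction
#' summaries average later.
#'
#' @param prevalence output of [compute_prevalence()].
#' @param sites site table from [sample_sites()] (needs `site_id`,
#'   `site_type`).
#' @param categories categories to keep; aircraft and `other` are excluded
#'   by default.
#' @return data.table with columns `site_id, date, period, category,
#'   prevalence, site_type`.
#' @export
model_table <- function(prevalence, sites,
                        categories = modeled_categories()) {
  pv <- as.data.table(prevalence)[category %in% categories]
  st <- as.data.table(sites)[, .(site_id, site_type)]
  out <- st[pv, on = "site_id"]
  if (anyNA(out$site_type))
    stop("prevalence records reference sites missing from the site table")
  out[, .(site_id, date, period, category, prevalence, site_type)]
}

#' Subsample fixed-site days
#'
#' Long-running fixed sites contribute many more dated rows than week-long
#' rotating sites; to avoid flooding the model with a handful of locations,
#' each fixed site is reduced to `min(n_days, available)` distinct dates,
#' sampled without replacement. Rotating rows are untouched.
#'
#' @param table a [model_table()].
#' @param n_days number of dates retained per fixed site (default 30).
#' @param seed integer seed for the date sampling.
#' @return The subsampled table (same columns).
#' @export
subsample_fixed_site_days <- function(table, n_days = 30, seed = 1L) {
  dt <- as.data.table(table)
  set.seed(seed)
  fixed_ids <- unique(dt[site_type == "fixed", site_id])
  keep <- rbindlist(lapply(fixed_ids, function(sid) {
    dates <- sort(unique(dt[site_id == sid, date]))
    data.table(site_id = sid,
               date = sort(sample(dates, min(n_days, length(dates)))))
  }))
  if (nrow(keep) == 0) return(dt)
  rbind(dt[site_type != "fixed"],
        dt[keep, on = c("site_id", "date")])[order(site_id, date, period,
                                                   category)]
}

#' Classifier validation against manual labels
#'
#' Per-category confusion counts and accuracy, positive predictive value
#' and negative predictive value (percent), comparing the classifier's
#' binary presence calls with manual labels on the same clips. Ratios with
#' a zero denominator (e.g. PPV with no predicted positives) are flagged
#' `NA`, never silently 0.
#'
#' @param predicted,manual logical/0-1 matrices or data.frames, rows =
#'   clips, columns = categories (same column names, same order of rows).
#' @return data.frame of class `classifier_validation` with columns
#'   `category, tp, fp, fn, tn, accuracy, ppv, npv, ppv_defined,
#'   npv_defined`.
#' @export
validate_classifier <- function(predicted, manual) {
  predicted <- as.matrix(predicted) > 0
  manual <- as.matrix(manual) > 0
  if (!identical(dim(predicted), dim(manual)))
    stop("predicted and manual labels must have identical dimensions")
  if (!identical(colnames(predicted), colnames(manual)))
    stop("predicted and manual labels must share category columns")
  res <- lapply(colnames(predicted), function(cc) {
    p <- predicted[, cc]; m <- manual[, cc]
    tp <- sum(p & m); fp <- sum(p & !m)
    fn <- sum(!p & m); tn <- sum(!p & !m)
    ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
    data.frame(category = cc, tp = tp, fp = fp, fn = fn, tn = tn,
               accuracy = ratio(tp + tn, tp + fp + fn + tn),
               ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn),
               ppv_defined = tp + fp > 0, npv_defined = tn + fn > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("classifier_validation", class(out))
  out
}

#' Clip and prevalence table CSV interchange
#'
#' Clips are stored as `site_id,timestamp,class1,class2,class3` with
#' minute-resolution timestamps; prevalence tables as
#' `site_id,date,period,category,n_clips,n_present,prevalence`. On read,
#' prevalence is recomputed from the integer counts, so a write/read
#' round-trip reproduces prevalences bit-exactly.
#'
#' @param clips,prevalence tables to write.
#' @param path file path.
#' @return Readers return data.tables; writers return `path` invisibly.
#' @export
write_clips_csv <- function(clips, path) {
  dt <- as.data.table(clips)
  dt <- dt[, .(site_id,
               timestamp = format(timestamp, "%Y-%m-%d %H:%M", tz = "UTC"),
               class1, class2, class3)]
  fwrite(dt, path)
  invisible(path)
}

#' @rdname write_clips_csv
#' @export
read_clips_csv <- function(path) {
  dt <- fread(path, colClasses = list(character = c(
    "site_id", "timestamp", "class1", "class2", "class3")))
  dt[, timestamp := as.POSIXct(timestamp, tz = "UTC",
                               format = "%Y-%m-%d %H:%M")]
  dt[, (c("class1", "class2", "class3")) := lapply(.SD, function(v) {
    v[v == ""] <- NA_character_; v
  }), .SDcols = c("class1", "class2", "class3")]
  dt[]
}

#' @rdname write_clips_csv
#' @export
write_prevalence_csv <- function(prevalence, path) {
  fwrite(as.data.table(prevalence), path)
  invisible(path)
}

#' @rdname write_clips_csv
#' @export
read_prevalence_csv <- function(path) {
  dt <- fread(path)
  dt[, date := as.Date(date)]
  dt[, prevalence := 100 * n_present / n_clips]
  dt[]
}
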