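test_that("clip classes map to overlapping categories, unknowns to other", {
  ont <- default_ontology()
  expect_setequal(
    map_clip_to_categories(c("vehicle_engine", "birdsong", "talking"), ont),
    c("road_transport", "animal_insect", "speech"))
  expect_equal(map_clip_to_categories("rain", ont), "geophysical_nature")
  expect_equal(map_clip_to_categories("zzz_unknown", ont), "other")
  # two fine labels of one category collapse to a single-element set
  expect_equal(map_clip_to_categories(c("talking", "laughter"), ont),
               "speech")
  expect_length(map_clip_to_categories(character(0), ont), 0)
})

test_that("period assignment matches the day/night windows exactly", {
  expect_equal(assign_period("21:59"), "day")
  expect_equal(assign_period("22:00"), "night")
  expect_equal(assign_period("05:59"), "night")
  expect_equal(assign_period("06:00"), "day")
  # every minute of the day falls in exactly one period: 16 h day, 8 h night
  mins <- sprintf("%02d:%02d", rep(0:23, each = 60), rep(0:59, 24))
  p <- assign_period(mins)
  expect_equal(sum(p == "day"), 16 * 60)
  expect_equal(sum(p == "night"), 8 * 60)
  # POSIXct input agrees with string input
  ts <- as.POSIXct("2019-04-10 22:00:00", tz = "UTC")
  expect_equal(assign_period(ts), "night")
})

make_clips <- function(times, classes, site = "S1",
                       day = as.Date("2019-04-10")) {
  data.table::data.table(
    site_id = site,
    timestamp = as.POSIXct(paste(day, times), tz = "UTC"),
    class1 = classes, class2 = NA_character_, class3 = NA_character_)
}

test_that("prevalence arithmetic is exact and 0/0-free", {
  # 96 day clips, category present in 48 -> exactly 50%
  times <- sprintf("%02d:%02d", rep(6:21, each = 6), rep(seq(0, 50, 10), 16))
  cls <- c(rep("vehicle_engine", 48), rep(NA_character_, 48))
  prev <- compute_prevalence(make_clips(times, cls))
  rt <- prev[prev$category == "road_transport", ]
  expect_equal(rt$n_clips, 96)
  expect_equal(rt$n_present, 48)
  expect_equal(rt$prevalence, 50.0)
  # absent categories get 0, present-in-all gets 100
  expect_equal(prev[prev$category == "music", ]$prevalence, 0.0)
  prev_all <- compute_prevalence(make_clips(times,
                                            rep("vehicle_engine", 96)))
  expect_equal(prev_all[prev_all$category == "road_transport", ]$prevalence,
               100.0)
  # no night rows were emitted at all (no night clips -> no 0/0 cell)
  expect_false("night" %in% prev$period)
})

test_that("night cells attach to the date the night begins", {
  times <- c(sprintf("22:%02d", seq(0, 50, 10)),
             sprintf("23:%02d", seq(0, 50, 10)))
  late <- make_clips(times, rep("birdsong", 12), day = as.Date("2019-04-10"))
  early <- make_clips(sprintf("0%d:%02d", rep(0:2, each = 6),
                              rep(seq(0, 50, 10), 3)),
                      rep("birdsong", 18), day = as.Date("2019-04-11"))
  prev <- compute_prevalence(rbind(late, early), min_clip_fraction = 0.5)
  # 12 + 18 = 30 clips, all in the night that begins on 2019-04-10
  nt <- prev[prev$period == "night" & prev$category == "animal_insect", ]
  expect_equal(nrow(nt), 1)
  expect_equal(as.character(nt$date), "2019-04-10")
  expect_equal(nt$n_clips, 30)
})

test_that("cells below the partial-day threshold are dropped", {
  # 40 of 96 scheduled day clips < half the schedule -> dropped
  times <- sprintf("%02d:%02d", rep(6:18, each = 6), rep(seq(0, 50, 10), 13))
  prev <- compute_prevalence(make_clips(times[1:40], rep("rain", 40)))
  expect_equal(nrow(prev), 0)
  # 50 of 96 passes
  prev2 <- compute_prevalence(make_clips(times[1:50], rep("rain", 50)))
  expect_gt(nrow(prev2), 0)
})

test_that("prevalence is invariant to clip order and round-trips via CSV", {
  city <- small_city()
  clips <- city$clips[city$clips$site_id %in%
                        unique(city$clips$site_id)[1:3], ]
  prev <- compute_prevalence(clips)
  set.seed(1)
  shuffled <- clips[sample(nrow(clips)), ]
  expect_equal(compute_prevalence(shuffled), prev)

  path <- withr::local_tempfile(fileext = ".csv")
  write_prevalence_csv(prev, path)
  back <- read_prevalence_csv(path)
  expect_identical(back$prevalence, prev$prevalence)
  expect_identical(back$n_present, prev$n_present)

  cpath <- withr::local_tempfile(fileext = ".csv")
  write_clips_csv(clips, cpath)
  clips_back <- read_clips_csv(cpath)
  expect_equal(compute_prevalence(clips_back), prev)
})

test_that("per-category n_present never exceeds n_clips but sums may", {
  city <- small_city()
  prev <- compute_prevalence(city$clips)
  expect_true(all(prev$n_present <= prev$n_clips))
  tot <- data.table::as.data.table(prev)[, .(
    s = sum(n_present), n = n_clips[1]), by = .(site_id, date, period)]
  expect_gt(max(tot$s / tot$n), 1)  # overlapping categories do occur
})

test_that("fixed-site days are subsampled to 30, rotating untouched", {
  dates <- as.Date("2019-01-01") + 0:299
  tab <- data.table::data.table(
    site_id = rep(c("F1", "R1"), c(300, 7)),
    date = c(dates, dates[1:7]),
    period = "day", category = "road_transport",
    prevalence = 50, site_type = rep(c("fixed", "rotating"), c(300, 7)))
  out <- subsample_fixed_site_days(tab, 30, seed = 3)
  expect_equal(sum(out$site_type == "fixed"), 30)
  expect_equal(sum(out$site_type == "rotating"), 7)
  expect_false(any(duplicated(out[out$site_type == "fixed", ]$date)))
  out2 <- subsample_fixed_site_days(tab, 30, seed = 3)
  expect_equal(out, out2)
  out3 <- subsample_fixed_site_days(tab, 30, seed = 4)
  expect_false(identical(out$date, out3$date))
})

test_that("classifier validation arithmetic is exact and flags undefined", {
  mk <- function(tp, fp, fn, tn) {
    pred <- c(rep(1, tp + fp), rep(0, fn + tn))
    man <- c(rep(1, tp), rep(0, fp), rep(1, fn), rep(0, tn))
    list(pred = matrix(pred, dimnames = list(NULL, "music")),
         man = matrix(man, dimnames = list(NULL, "music")))
  }
  x <- mk(10, 0, 0, 5)
  r <- validate_classifier(x$pred, x$man)
  expect_equal(c(r$accuracy, r$ppv, r$npv), c(100, 100, 100))

  # n = 150 confusion table: accuracy 96.7, PPV 80.0, NPV 97.9
  y <- mk(8, 2, 3, 137)
  r2 <- validate_classifier(y$pred, y$man)
  expect_equal(r2$accuracy, 100 * 145 / 150, tolerance = 1e-12)
  expect_equal(r2$ppv, 80.0)
  expect_equal(r2$npv, 100 * 137 / 140, tolerance = 1e-12)
  expect_equal(round(c(r2$accuracy, r2$ppv, r2$npv), 1),
               c(96.7, 80.0, 97.9))

  # all-negative predictions: PPV undefined and flagged, NPV computed
  z <- mk(0, 0, 4, 10)
  r3 <- validate_classifier(z$pred, z$man)
  expect_true(is.na(r3$ppv))
  expect_false(r3$ppv_defined)
  expect_equal(r3$npv, 100 * 10 / 14, tolerance = 1e-12)
})
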