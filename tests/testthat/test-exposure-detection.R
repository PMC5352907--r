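make_weather <- function(dates, tmax, county = "Union", precip = 0) {
  tibble::tibble(county = county, date = dates, tmax_f = tmax,
                 precip_in = precip)
}

test_that("a three-day run at 96 degF is detected as one inclusive-duration event", {
  dates <- seq(as.Date("2000-08-01"), as.Date("2000-09-15"), by = "day")
  tmax <- rep(90, length(dates))
  hot <- dates >= as.Date("2000-08-28") & dates <= as.Date("2000-08-30")
  tmax[hot] <- 96
  ev <- detect_heat_events(make_weather(dates, tmax))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start, as.Date("2000-08-28"))
  expect_equal(ev$end, as.Date("2000-08-30"))
  expect_equal(ev$duration_days, 3L)
  expect_equal(ev$peak_tmax_f, 96)
})

test_that("threshold is inclusive but short runs and sub-threshold summers yield no events", {
  dates <- seq(as.Date("2005-06-01"), as.Date("2005-08-31"), by = "day")
  # exactly two consecutive days at exactly 95.0
  tmax <- rep(90, length(dates))
  tmax[40:41] <- 95.0
  expect_equal(nrow(detect_heat_events(make_weather(dates, tmax))), 0)
  # three days at 95.0 qualify (inclusive comparison)
  tmax[40:42] <- 95.0
  expect_equal(nrow(detect_heat_events(make_weather(dates, tmax))), 1)
  # constant 94.9 never reaches the threshold
  expect_equal(nrow(detect_heat_events(make_weather(dates, rep(94.9, length(dates))))), 0)
})

test_that("missing days break runs and out-of-season days never qualify", {
  dates <- seq(as.Date("2012-09-25"), as.Date("2012-10-10"), by = "day")
  tmax <- rep(97, length(dates))
  ev <- detect_heat_events(make_weather(dates, tmax))
  # only Sep 25-30 is in season
  expect_equal(nrow(ev), 1)
  expect_equal(ev$end, as.Date("2012-09-30"))
  expect_equal(ev$duration_days, 6L)

  dates2 <- seq(as.Date("2012-07-01"), as.Date("2012-07-10"), by = "day")
  tmax2 <- rep(97, 10)
  tmax2[5] <- NA
  ev2 <- detect_heat_events(make_weather(dates2, tmax2))
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$duration_days, c(4L, 5L))
})

test_that("unsorted or duplicated dates and non-Fahrenheit units are input errors", {
  w <- make_weather(as.Date(c("2012-07-02", "2012-07-01")), c(96, 96))
  expect_error(detect_heat_events(w), "sorted")
  w2 <- make_weather(as.Date(c("2012-07-01", "2012-07-01")), c(96, 96))
  expect_error(detect_heat_events(w2), "Duplicate")
  w3 <- make_weather(as.Date("2012-07-01") + 0:3, rep(96, 4))
  attr(w3, "temp_units") <- "C"
  expect_error(detect_heat_events(w3), "Fahrenheit")
  expect_error(detection_params(temp_units = "C"), "Fahrenheit")
})

test_that("detection matches the exhaustive-window oracle on random series", {
  for (seed in 1:60) {
    w <- random_weather(seed)
    got <- detect_heat_events(w)
    exp <- oracle_heat_events(w$date, w$tmax_f)
    expect_equal(nrow(got), nrow(exp), info = paste("seed", seed))
    if (nrow(exp) > 0) {
      expect_equal(got$start, exp$start, info = paste("seed", seed))
      expect_equal(got$end, exp$end, info = paste("seed", seed))
    }
  }
})

test_that("every detected event is maximal, inclusive-threshold, and long enough", {
  params <- detection_params()
  for (seed in 101:130) {
    w <- random_weather(seed)
    ev <- detect_heat_events(w, params)
    for (i in seq_len(nrow(ev))) {
      days <- seq(ev$start[i], ev$end[i], by = "day")
      vals <- w$tmax_f[match(days, w$date)]
      expect_true(all(!is.na(vals) & vals >= params$heat_threshold))
      expect_gte(length(days), params$min_run)
      # extending one day in either direction must fail threshold, season
      # or availability
      for (d in c(ev$start[i] - 1, ev$end[i] + 1)) {
        v <- w$tmax_f[match(d, w$date)]
        extendable <- !is.na(match(d, w$date)) && !is.na(v) &&
          v >= params$heat_threshold && md_in_season(d)
        expect_false(isTRUE(extendable))
      }
    }
  }
})

test_that("raising the threshold or minimum run never adds events", {
  for (seed in 201:220) {
    w <- random_weather(seed)
    n_base <- nrow(detect_heat_events(w, detection_params()))
    expect_lte(nrow(detect_heat_events(w, detection_params(heat_threshold = 97))), n_base)
    expect_lte(nrow(detect_heat_events(w, detection_params(min_run = 4))), n_base)
  }
})

test_that("heavy precipitation days use a strict threshold and count per year", {
  dates <- seq(as.Date("2011-01-01"), as.Date("2011-12-31"), by = "day")
  p <- rep(0, length(dates))
  w <- make_weather(dates, 70, precip = p)
  expect_equal(count_heavy_precip_days(w, year = 2011)$heavy_precip_days, 0L)
  p[100] <- 2.0 # exactly at threshold: "over 2 inches" is strict
  w$precip_in <- p
  expect_equal(count_heavy_precip_days(w, year = 2011)$heavy_precip_days, 0L)
  p[c(120, 150)] <- c(2.5, 3.1)
  w$precip_in <- p
  expect_equal(count_heavy_precip_days(w, year = 2011)$heavy_precip_days, 2L)
  # lowering the threshold never decreases the count
  lower <- count_heavy_precip_days(w, detection_params(precip_threshold = 1.5),
                                   year = 2011)$heavy_precip_days
  expect_gte(lower, 2L)
})

test_that("drought spells are maximal D2+ runs with the peak recorded", {
  d <- tibble::tibble(county = "Union",
                      week_start = as.Date("2012-07-02") + 7 * (0:4),
                      category = c("D1", "D2", "D3", "D2", "D1"))
  sp <- extract_drought_spells(d)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$n_weeks, 3L)
  expect_equal(sp$peak_category, "D3")
  expect_equal(sp$start_week, as.Date("2012-07-09"))

  all_d1 <- d
  all_d1$category <- "D1"
  expect_equal(nrow(extract_drought_spells(all_d1)), 0)
})

test_that("spell extraction matches the week-scan oracle on random series", {
  for (seed in 1:80) {
    d <- random_drought(seed)
    got <- extract_drought_spells(d)
    exp <- oracle_drought_spells(d$week_start, d$category)
    expect_equal(nrow(got), nrow(exp), info = paste("seed", seed))
    if (nrow(exp) > 0) {
      expect_equal(got$start_week, exp$start_week)
      expect_equal(got$end_week, exp$end_week)
      expect_equal(got$peak_category, exp$peak_category)
    }
  }
})

test_that("a gap in the weekly grid breaks a spell", {
  d <- tibble::tibble(county = "A",
                      week_start = as.Date("2012-06-04") + c(0, 7, 21, 28),
                      category = c("D2", "D2", "D2", "D2"))
  sp <- extract_drought_spells(d)
  expect_equal(nrow(sp), 2)
  expect_equal(sp$n_weeks, c(2L, 2L))
})

test_that("overlap counting distinguishes containment from intersection", {
  events <- tibble::tibble(start = as.Date(c("2012-06-27", "2012-07-15")),
                           end = as.Date(c("2012-07-10", "2012-08-09")))
  win <- as.Date(c("2012-07-01", "2012-08-31"))
  # first event straddles the window start: only the contained one counts
  expect_equal(overlap_days(events, win), 26L)
  expect_equal(overlap_days(events, win, policy = "intersection"), 36L)
  # fully disjoint events contribute nothing
  far <- tibble::tibble(start = as.Date("2011-07-01"), end = as.Date("2011-07-05"))
  expect_equal(overlap_days(far, win), 0L)
})

test_that("overlap counting matches the per-day oracle on random inputs", {
  for (seed in 1:50) {
    set.seed(seed)
    n_ev <- sample(1:5, 1)
    starts <- as.Date("2012-06-01") + sample(0:80, n_ev)
    events <- tibble::tibble(start = starts, end = starts + sample(2:10, n_ev, replace = TRUE))
    win <- sort(as.Date("2012-06-15") + sample(0:70, 2))
    for (policy in c("containment", "intersection")) {
      expect_equal(overlap_days(events, win, policy = policy),
                   oracle_overlap(events, win, policy = policy),
                   info = paste("seed", seed, policy))
    }
  }
})

test_that("district consolidation merges overlapping windows and annotates near misses", {
  dates <- seq(as.Date("2007-07-01"), as.Date("2007-09-15"), by = "day")
  wA <- make_weather(dates, ifelse(dates >= as.Date("2007-07-31") &
                                     dates <= as.Date("2007-08-24"), 97, 90),
                     county = "A")
  wB <- make_weather(dates, ifelse(dates >= as.Date("2007-08-05") &
                                     dates <= as.Date("2007-08-06"), 96, 90),
                     county = "B")
  w <- rbind(wA, wB)
  ev <- detect_heat_events(w)
  runs <- heat_runs(w)
  dist <- consolidate_district_events(ev, runs)
  expect_equal(nrow(dist), 1)
  expect_equal(dist$counties_affected[[1]], "A")
  expect_equal(dist$near_threshold[[1]]$county, "B")
  expect_equal(dist$near_threshold[[1]]$length, 2L)

  # single county, single event: no annotations
  distA <- consolidate_district_events(detect_heat_events(wA), heat_runs(wA))
  expect_equal(nrow(distA), 1)
  expect_equal(nrow(distA$near_threshold[[1]]), 0)
})

test_that("identical county windows merge into one district event; gaps of one day or more do not", {
  ev3 <- tibble::tibble(
    county = c("A", "B", "C"),
    start = as.Date("2012-07-01"), end = as.Date("2012-07-05"),
    duration_days = 5L, peak_tmax_f = 97
  )
  dist <- consolidate_district_events(ev3)
  expect_equal(nrow(dist), 1)
  expect_setequal(dist$counties_affected[[1]], c("A", "B", "C"))

  # abutting windows (gap 0: next starts the day after) merge
  ev_ab <- tibble::tibble(county = c("A", "B"),
                          start = as.Date(c("2012-07-01", "2012-07-06")),
                          end = as.Date(c("2012-07-05", "2012-07-09")),
                          duration_days = c(5L, 4L), peak_tmax_f = 97)
  expect_equal(nrow(consolidate_district_events(ev_ab)), 1)

  # a one-day gap keeps them separate
  ev_gap <- ev_ab
  ev_gap$start[2] <- as.Date("2012-07-07")
  expect_equal(nrow(consolidate_district_events(ev_gap)), 2)
})

test_that("empty series produce empty results, not errors", {
  empty <- tibble::tibble(county = character(), date = as.Date(character()),
                          tmax_f = double(), precip_in = double())
  expect_equal(nrow(detect_heat_events(empty)), 0)
  expect_equal(nrow(heat_runs(empty)), 0)
  empty_d <- tibble::tibble(county = character(),
                            week_start = as.Date(character()),
                            category = character())
  expect_equal(nrow(extract_drought_spells(empty_d)), 0)
})
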