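#' Detection parameters for hazard exposure
#'
#' Bundles the thresholds that define hazard exposure for a district:
#' extreme heat is a run of at least `min_run` consecutive in-season days
#' with daily maximum temperature at or above `heat_threshold` (the
#' comparison is inclusive: exactly 95.0 degF qualifies); a heavy
#' precipitation day has recorded precipitation strictly over
#' `precip_threshold`; drought exposure is a week at or above
#' `drought_min_severity` on the US Drought Monitor scale.
#'
#' @param heat_threshold Daily maximum temperature threshold in degF
#'   (default 95).
#' @param min_run Minimum number of consecutive qualifying days for an
#'   extreme heat event (default 3).
#' @param season Two `"mm-dd"` strings giving the start and end of the heat
#'   season; qualifying days are counted only inside this window
#'   (default May 1 to September 30).
#' @param precip_threshold Heavy-precipitation threshold in inches,
#'   exceeded strictly (default 2.0).
#' @param drought_min_severity Minimum US Drought Monitor category that
#'   counts as drought exposure (default `"D2"`, severe).
#' @param temp_units Temperature units of the input series; only `"F"` is
#'   supported, and a series declaring different units is an error.
#' @return An object of class `detection_params`.
#' @export
#' @examples
#' detection_params()
#' detection_params(heat_threshold = 100, min_run = 2)
detection_params <- function(heat_threshold = 95,
                             min_run = 3L,
                             season = c("05-01", "09-30"),
                             precip_threshold = 2.0,
                             drought_min_severity = "D2",
                             temp_units = "F") {
  stopifnot(
    is.numeric(heat_threshold), length(heat_threshold) == 1, is.finite(heat_threshold),
    is.numeric(min_run), length(min_run) == 1, min_run >= 1,
    is.character(season), length(season) == 2,
    is.numeric(precip_threshold), length(precip_threshold) == 1, is.finite(precip_threshold)
  )
  if (season[1] > season[2]) {
    abort("Season start must not be after season end within a year")
  }
  if (!identical(temp_units, "F")) {
    abort("Only Fahrenheit input is supported; convert series before detection")
  }
  drought_level(drought_min_severity)
  structure(
    list(
      heat_threshold = heat_threshold,
      min_run = as.integer(min_run),
      season = season,
      precip_threshold = precip_threshold,
      drought_min_severity = toupper(drought_min_severity),
      temp_units = temp_units
    ),
    class = "detection_params"
  )
}

#' @export
print.detection_params <- function(x, ...) {
  cat("Hazard detection parameters\n")
  cat(sprintf("  extreme heat : tmax >= %g degF for >= %d consecutive days, season %s..%s\n",
              x$heat_threshold, x$min_run, x$season[1], x$season[2]))
  cat(sprintf("  heavy precip : > %g inches in a day\n", x$precip_threshold))
  cat(sprintf("  drought      : week at >= %s (US Drought Monitor)\n", x$drought_min_severity))
  invisible(x)
}

validate_weather <- function(weather, stage = "weather") {
  req <- c("county", "date", "tmax_f", "precip_in")
  missing_cols <- setdiff(req, names(weather))
  if (length(missing_cols) > 0) {
    stop_stage(stage, paste("Missing columns:", paste(missing_cols, collapse = ", ")))
  }
  units <- attr(weather, "temp_units") %||% "F"
  if (!identical(units, "F")) {
    stop_stage(stage, paste0("Series declares temperature units \"", units,
                             "\"; only Fahrenheit is supported"))
  }
  by_cty <- split(weather$date, weather$county)
  for (cty in names(by_cty)) {
    d <- by_cty[[cty]]
    if (anyDuplicated(d)) {
      stop_stage(stage, paste0("Duplicate dates for county ", cty))
    }
    if (is.unsorted(d)) {
      stop_stage(stage, paste0("Dates not sorted for county ", cty))
    }
  }
  tmax <- weather$tmax_f
  if (any(!is.na(tmax) & (tmax < -50 | tmax > 130))) {
    stop_stage(stage, "tmax_f outside plausible range [-50, 130] degF")
  }
  if (any(!is.na(weather$precip_in) & weather$precip_in < 0)) {
    stop_stage(stage, "Negative precipitation")
  }
  invisible(weather)
}

# Per-county maximal runs of qualifying days (any length >= 1).
# A day qualifies when it is in season, observed (non-missing tmax), and
# tmax >= threshold. Gaps in the date coverage and missing values break
# runs: an unobserved day is never assumed hot.
heat_runs_one <- function(dates, tmax, params) {
  if (length(dates) == 0) {
    return(tibble(start = as.Date(character()), end = as.Date(character()),
                  length = integer(), peak_tmax_f = double()))
  }
  grid <- seq(min(dates), max(dates), by = "day")
  val <- rep(NA_real_, length(grid))
  val[match(dates, grid)] <- tmax
  qual <- !is.na(val) & val >= params$heat_threshold & in_season(grid, params$season)
  runs <- true_runs(qual)
  tibble(
    start = grid[runs$start_idx],
    end = grid[runs$end_idx],
    length = runs$length,
    peak_tmax_f = vapply(seq_len(nrow(runs)), function(i) {
      max(val[runs$start_idx[i]:runs$end_idx[i]])
    }, double(1))
  )
}

#' All maximal runs of qualifying hot days, any length
#'
#' Returns every maximal run of consecutive in-season days at or above the
#' heat threshold, including runs shorter than `min_run`. Near-threshold
#' runs (length `min_run - 1`) feed the district consolidation annotations;
#' [detect_heat_events()] keeps only runs of qualifying length.
#'
#' @param weather Daily weather tibble (`county`, `date`, `tmax_f`,
#'   `precip_in`).
#' @param params A [detection_params()] object.
#' @return A tibble with columns `county`, `start`, `end`, `length`,
#'   `peak_tmax_f`, sorted by county and start date.
#' @export
heat_runs <- function(weather, params = detection_params()) {
  validate_weather(weather)
  out <- lapply(split(weather, weather$county), function(df) {
    runs <- heat_runs_one(df$date, df$tmax_f, params)
    if (nrow(runs) > 0) runs$county <- df$county[1]
    runs
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(county = character(), start = as.Date(character()),
                  end = as.Date(character()), length = integer(),
                  peak_tmax_f = double()))
  }
  arrange(select(out, all_of(c("county", "start", "end", "length", "peak_tmax_f"))),
          .data$county, .data$start)
}

#' Detect extreme heat events in a daily weather series
#'
#' An extreme heat event is a maximal run of at least `min_run` consecutive
#' in-season days whose daily maximum temperature is at or above the heat
#' threshold (inclusive: exactly the threshold qualifies). Days outside the
#' season never qualify, so a run straddling the season boundary is clipped
#' to its in-season portion; missing daily values break runs.
#'
#' @inheritParams heat_runs
#' @return A tibble of events with columns `county`, `start`, `end`,
#'   `duration_days`, `peak_tmax_f`, sorted by county and start date.
#'   Events within a county are non-overlapping and maximal. An empty
#'   series yields an empty tibble.
#' @export
#' @examples
#' w <- tibble::tibble(
#'   county = "Union",
#'   date = seq(as.Date("2000-08-20"), as.Date("2000-09-05"), by = "day"),
#'   tmax_f = 90, precip_in = 0
#' )
#' w$tmax_f[w$date >= as.Date("2000-08-28") & w$date <= as.Date("2000-08-30")] <- 96
#' detect_heat_events(w)
detect_heat_events <- function(weather, params = detection_params()) {
  runs <- heat_runs(weather, params)
  events <- filter(runs, .data$length >= params$min_run)
  events <- rename(events, duration_days = "length")
  arrange(events, .data$county, .data$start)
}

#' Consolidate county heat events into district events
#'
#' County events whose date ranges overlap or abut (a gap of zero days:
#' one window starts the day after the other ends) are merged into a
#' district event spanning the union of their ranges. Each district event
#' lists the counties that contributed a qualifying event
#' (`counties_affected`) and annotates counties that only reached the
#' threshold for `min_run - 1` consecutive days overlapping the window
#' (`near_threshold`), mirroring the "reached threshold for 2 days"
#' footnote convention.
#'
#' @param events County heat events from [detect_heat_events()].
#' @param runs All maximal qualifying runs from [heat_runs()] (so that
#'   near-miss runs are visible to the annotation).
#' @param params A [detection_params()] object.
#' @return A tibble with columns `start`, `end`, `counties_affected`
#'   (list of character vectors) and `near_threshold` (list of tibbles
#'   with `county` and `length`), sorted by start date.
#' @export
consolidate_district_events <- function(events, runs = NULL,
                                        params = detection_params()) {
  if (nrow(events) == 0) {
    return(tibble(start = as.Date(character()), end = as.Date(character()),
                  counties_affected = list(), near_threshold = list()))
  }
  ev <- arrange(events, .data$start, .data$end)
  # merge overlapping or abutting windows
  starts <- ev$start
  ends <- ev$end
  grp <- integer(nrow(ev))
  grp[1] <- 1L
  cur_end <- ends[1]
  for (i in seq_len(nrow(ev))[-1]) {
    if (starts[i] <= cur_end + 1) {
      grp[i] <- grp[i - 1]
      cur_end <- max(cur_end, ends[i])
    } else {
      grp[i] <- grp[i - 1] + 1L
      cur_end <- ends[i]
    }
  }
  near_len <- params$min_run - 1L
  out <- lapply(split(seq_len(nrow(ev)), grp), function(idx) {
    w_start <- min(starts[idx])
    w_end <- max(ends[idx])
    affected <- sort(unique(ev$county[idx]))
    near <- tibble(county = character(), length = integer())
    if (!is.null(runs) && near_len >= 1) {
      cand <- filter(
        runs,
        .data$length == near_len,
        .data$start <= w_end, .data$end >= w_start,
        !.data$county %in% affected
      )
      if (nrow(cand) > 0) {
        near <- distinct(select(arrange(cand, .data$county), all_of(c("county", "length"))))
      }
    }
    tibble(start = w_start, end = w_end,
           counties_affected = list(affected), near_threshold = list(near))
  })
  arrange(bind_rows(out), .data$start)
}

#' Count heavy precipitation days in a calendar year
#'
#' A heavy precipitation day has recorded precipitation strictly over the
#' threshold ("over 2 inches"): a day at exactly the threshold does not
#' count, and missing days contribute nothing.
#'
#' @inheritParams heat_runs
#' @param year Calendar year (integer); `NULL` counts every year present.
#' @return A tibble with columns `county`, `year`, `heavy_precip_days`.
#' @export
#' @examples
#' w <- tibble::tibble(county = "Daviess",
#'   date = as.Date("2011-04-01") + 0:9,
#'   tmax_f = 70, precip_in = c(2.5, 3.1, rep(0, 8)))
#' count_heavy_precip_days(w, year = 2011)
count_heavy_precip_days <- function(weather, params = detection_params(),
                                    year = NULL) {
  validate_weather(weather)
  df <- mutate(weather, year = as.integer(format(.data$date, "%Y")))
  if (!is.null(year)) {
    yr <- as.integer(year)
    df <- filter(df, .data$year %in% yr)
    base <- tidyr::expand_grid(county = unique(weather$county), year = yr)
  } else {
    base <- distinct(select(df, all_of(c("county", "year"))))
  }
  counts <- summarise(
    group_by(df, .data$county, .data$year),
    heavy_precip_days = sum(!is.na(.data$precip_in) &
                              .data$precip_in > params$precip_threshold),
    .groups = "drop"
  )
  out <- left_join(base, counts, by = c("county", "year"))
  out$heavy_precip_days[is.na(out$heavy_precip_days)] <- 0L
  arrange(out, .data$county, .data$year)
}

validate_drought <- function(drought, stage = "drought") {
  req <- c("county", "week_start", "category")
  missing_cols <- setdiff(req, names(drought))
  if (length(missing_cols) > 0) {
    stop_stage(stage, paste("Missing columns:", paste(missing_cols, collapse = ", ")))
  }
  drought_level(drought$category)
  by_cty <- split(drought$week_start, drought$county)
  for (cty in names(by_cty)) {
    w <- by_cty[[cty]]
    if (anyDuplicated(w)) stop_stage(stage, paste0("Duplicate weeks for county ", cty))
    if (is.unsorted(w)) stop_stage(stage, paste0("Weeks not sorted for county ", cty))
  }
  invisible(drought)
}

#' Extract drought spells from a weekly category series
#'
#' A drought spell is a maximal run of consecutive weeks (week starts 7
#' days apart) at or above the minimum severity category (default D2,
#' severe). The peak category reached during the spell is recorded.
#'
#' @param drought Weekly drought tibble (`county`, `week_start`,
#'   `category`).
#' @param params A [detection_params()] object.
#' @return A tibble with columns `county`, `start_week`, `end_week`,
#'   `n_weeks`, `peak_category`, sorted by county and start week.
#' @export
#' @examples
#' d <- tibble::tibble(county = "Union",
#'   week_start = as.Date("2012-07-03") + 7 * (0:4),
#'   category = c("D1", "D2", "D3", "D2", "D1"))
#' extract_drought_spells(d)
extract_drought_spells <- function(drought, params = detection_params()) {
  validate_drought(drought)
  min_level <- drought_level(params$drought_min_severity)
  out <- lapply(split(drought, drought$county), function(df) {
    df <- arrange(df, .data$week_start)
    if (nrow(df) == 0) return(NULL)
    # a >7-day jump between week starts breaks consecutiveness
    gap_break <- c(FALSE, diff(df$week_start) != 7)
    seg <- cumsum(gap_break)
    lev <- drought_level(df$category)
    res <- lapply(split(seq_len(nrow(df)), seg), function(idx) {
      q <- lev[idx] >= min_level
      runs <- true_runs(q)
      if (nrow(runs) == 0) return(NULL)
      tibble(
        county = df$county[1],
        start_week = df$week_start[idx][runs$start_idx],
        end_week = df$week_start[idx][runs$end_idx],
        n_weeks = runs$length,
        peak_category = vapply(seq_len(nrow(runs)), function(i) {
          span <- idx[runs$start_idx[i]:runs$end_idx[i]]
          DROUGHT_CATEGORIES[max(lev[span]) + 1L]
        }, character(1))
      )
    })
    bind_rows(res)
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    return(tibble(county = character(), start_week = as.Date(character()),
                  end_week = as.Date(character()), n_weeks = integer(),
                  peak_category = character()))
  }
  arrange(out, .data$county, .data$start_week)
}

#' Expand drought spells or weeks to daily dates
#'
#' Each week covers the 7 days starting at its week-start date.
#'
#' @param spells A spell tibble from [extract_drought_spells()].
#' @return A sorted vector of unique `Date`s covered by the spells.
#' @export
spell_days <- function(spells) {
  if (nrow(spells) == 0) return(as.Date(character()))
  days <- unlist(lapply(seq_len(nrow(spells)), function(i) {
    seq(spells$start_week[i], spells$end_week[i] + 6, by = "day")
  }))
  sort(unique(as.Date(days, origin = "1970-01-01")))
}

event_days <- function(events) {
  if (nrow(events) == 0) return(as.Date(character()))
  days <- unlist(lapply(seq_len(nrow(events)), function(i) {
    seq(events$start[i], events$end[i], by = "day")
  }))
  sort(unique(as.Date(days, origin = "1970-01-01")))
}

#' Count heat-event days overlapping a drought period
#'
#' Counts distinct calendar days covered by at least one heat event and
#' lying inside a drought period. The period is either an explicit date
#' window (`c(start, end)`), a vector of covered dates, or a spell tibble
#' from [extract_drought_spells()] (expanded to daily dates).
#'
#' Two containment policies are offered. Under `"containment"` (the
#' default) an event contributes its days only if the whole event lies
#' inside the period; under `"intersection"` each event day inside the
#' period counts, regardless of where the rest of the event falls.
#'
#' @param events Heat events (district or county) with `start` and `end`
#'   columns.
#' @param period A length-2 `Date` window, a `Date` vector of covered
#'   days, or a drought-spell tibble.
#' @param policy `"containment"` or `"intersection"`.
#' @return Integer count of distinct overlapping days.
#' @export
overlap_days <- function(events, period,
                         policy = c("containment", "intersection")) {
  policy <- match.arg(policy)
  if (is.data.frame(period)) {
    days <- spell_days(period)
  } else {
    period <- as_date_strict(period, "period")
    days <- if (length(period) == 2) {
      seq(period[1], period[2], by = "day")
    } else {
      sort(unique(period))
    }
  }
  if (nrow(events) == 0 || length(days) == 0) return(0L)
  if (policy == "containment") {
    keep <- vapply(seq_len(nrow(events)), function(i) {
      ev <- seq(events$start[i], events$end[i], by = "day")
      all(ev %in% days)
    }, logical(1))
    covered <- event_days(events[keep, , drop = FALSE])
    length(covered)
  } else {
    covered <- event_days(events)
    sum(covered %in% days)
  }
}
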