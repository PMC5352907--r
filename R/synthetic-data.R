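#' Configuration for the synthetic daily weather generator
#'
#' Describes a Western-Kentucky-like summer weather simulation: a baseline
#' daily maximum temperature with Gaussian day-to-day noise, intermittent
#' precipitation, and optionally embedded heat runs (consecutive days
#' pushed to a fixed offset above the extreme-heat threshold) and
#' heavy-precipitation days. A noise spread of zero is allowed so that
#' construction-exact tests are possible.
#'
#' @param counties Character vector of county identifiers.
#' @param start,end Calendar dates bounding the series (inclusive).
#' @param baseline_tmax_mean Mean daily maximum temperature, degF
#'   (default 86, a typical district July).
#' @param baseline_tmax_sd Day-to-day noise standard deviation, degF
#'   (default 6; 0 gives a flat deterministic baseline).
#' @param precip_prob Per-day probability of any precipitation
#'   (default 0.3).
#' @param precip_mean Mean precipitation on a wet day, inches (default
#'   0.3; amounts are exponential, so multi-inch days are rare but
#'   possible).
#' @param heat_threshold The extreme-heat threshold embedded runs are
#'   raised above, degF (default 95).
#' @param embedded_heat_runs Tibble with columns `county`, `start`,
#'   `length`, `offset`: each run sets `length` consecutive days to
#'   `heat_threshold + offset` degF.
#' @param embedded_precip_days Tibble with columns `county`, `date`,
#'   `inches`: each row forces that day's precipitation.
#' @param seed Integer random seed.
#' @return A `weather_sim_config` object.
#' @export
weather_sim_config <- function(counties, start, end,
                               baseline_tmax_mean = 86,
                               baseline_tmax_sd = 6,
                               precip_prob = 0.3,
                               precip_mean = 0.3,
                               heat_threshold = 95,
                               embedded_heat_runs = NULL,
                               embedded_precip_days = NULL,
                               seed = 1L) {
  start <- as_date_strict(start, "start")
  end <- as_date_strict(end, "end")
  if (start > end) abort("date_range start must not be after end")
  stopifnot(length(counties) >= 1, baseline_tmax_sd >= 0,
            precip_prob >= 0, precip_prob <= 1, precip_mean > 0)
  runs <- embedded_heat_runs %||%
    tibble(county = character(), start = as.Date(character()),
           length = integer(), offset = double())
  runs$start <- as_date_strict(runs$start, "run start")
  if (nrow(runs) > 0) {
    if (any(runs$length < 1)) abort("Embedded run lengths must be >= 1")
    if (any(!runs$county %in% counties)) abort("Embedded run county not in counties")
    run_end <- runs$start + runs$length - 1
    if (any(runs$start < start | run_end > end)) {
      abort("Embedded heat run outside the configured date range")
    }
    if (any(runs$offset < 0)) abort("Embedded run offsets must be >= 0")
  }
  pdays <- embedded_precip_days %||%
    tibble(county = character(), date = as.Date(character()), inches = double())
  pdays$date <- as_date_strict(pdays$date, "precip day")
  if (nrow(pdays) > 0) {
    if (any(pdays$date < start | pdays$date > end)) {
      abort("Embedded precipitation day outside the configured date range")
    }
    if (any(pdays$inches < 0)) abort("Embedded precipitation must be >= 0")
  }
  structure(
    list(counties = counties, start = start, end = end,
         baseline_tmax_mean = baseline_tmax_mean,
         baseline_tmax_sd = baseline_tmax_sd,
         precip_prob = precip_prob, precip_mean = precip_mean,
         heat_threshold = heat_threshold,
         embedded_heat_runs = runs, embedded_precip_days = pdays,
         seed = as.integer(seed)),
    class = "weather_sim_config"
  )
}

#' Generate synthetic daily weather series
#'
#' One series per county covering every date in the configured range.
#' Embedded heat runs force daily maxima to exactly
#' `heat_threshold + offset` degF on their days; embedded precipitation
#' days force the stated amount. Identical configuration and seed give
#' identical output.
#'
#' @param config A [weather_sim_config()] object.
#' @return A weather tibble (`county`, `date`, `tmax_f`, `precip_in`)
#'   carrying a `temp_units = "F"` attribute.
#' @export
#' @examples
#' cfg <- weather_sim_config("A", "2012-06-01", "2012-08-31",
#'   baseline_tmax_sd = 0, baseline_tmax_mean = 80,
#'   embedded_heat_runs = tibble::tibble(
#'     county = "A", start = as.Date("2012-07-01"), length = 3, offset = 1))
#' w <- gen_weather(cfg)
#' sum(w$tmax_f >= 95)
gen_weather <- function(config) {
  stopifnot(inherits(config, "weather_sim_config"))
  withr::with_seed(config$seed, {
    dates <- seq(config$start, config$end, by = "day")
    out <- bind_rows(lapply(config$counties, function(cty) {
      n <- length(dates)
      tmax <- config$baseline_tmax_mean +
        if (config$baseline_tmax_sd > 0) rnorm(n, 0, config$baseline_tmax_sd) else 0
      wet <- rbinom(n, 1, config$precip_prob) == 1
      precip <- ifelse(wet, stats::rexp(n, rate = 1 / config$precip_mean), 0)
      tibble(county = cty, date = dates, tmax_f = tmax, precip_in = precip)
    }))
    runs <- config$embedded_heat_runs
    for (i in seq_len(nrow(runs))) {
      days <- seq(runs$start[i], runs$start[i] + runs$length[i] - 1, by = "day")
      sel <- out$county == runs$county[i] & out$date %in% days
      out$tmax_f[sel] <- config$heat_threshold + runs$offset[i]
    }
    pdays <- config$embedded_precip_days
    for (i in seq_len(nrow(pdays))) {
      sel <- out$county == pdays$county[i] & out$date == pdays$date[i]
      out$precip_in[sel] <- pdays$inches[i]
    }
    out <- arrange(out, .data$county, .data$date)
    attr(out, "temp_units") <- "F"
    out
  })
}

#' Generate synthetic weekly drought-category series
#'
#' Background weeks stay below D2 (sampled from NONE/D0/D1); each embedded
#' spell places a run of weeks at or above D2 that reaches its stated peak
#' category (the peak is placed mid-spell, with D2 shoulders).
#'
#' @param counties Character vector of county identifiers.
#' @param start,end Dates bounding the weekly grid; weeks start at `start`
#'   and step by 7 days.
#' @param embedded_spells Tibble with columns `county`, `start_week`,
#'   `n_weeks`, `peak` (a category in D2..D4). Week starts must lie on the
#'   weekly grid.
#' @param seed Integer random seed.
#' @return A drought tibble (`county`, `week_start`, `category`).
#' @export
gen_drought <- function(counties, start, end, embedded_spells = NULL,
                        seed = 1L) {
  start <- as_date_strict(start, "start")
  end <- as_date_strict(end, "end")
  if (start > end) abort("date_range start must not be after end")
  weeks <- seq(start, end, by = "7 days")
  spells <- embedded_spells %||%
    tibble(county = character(), start_week = as.Date(character()),
           n_weeks = integer(), peak = character())
  spells$start_week <- as_date_strict(spells$start_week, "spell start")
  if (nrow(spells) > 0) {
    if (any(drought_level(spells$peak) < drought_level("D2"))) {
      abort("Embedded spell peaks must be D2 or worse")
    }
    if (any(spells$n_weeks < 1)) abort("Spell lengths must be >= 1")
    if (any(!spells$start_week %in% weeks)) {
      abort("Spell start weeks must lie on the weekly grid")
    }
    spell_end <- spells$start_week + 7 * (spells$n_weeks - 1)
    if (any(spell_end > max(weeks))) abort("Embedded spell outside the date range")
  }
  withr::with_seed(as.integer(seed), {
    out <- bind_rows(lapply(counties, function(cty) {
      tibble(
        county = cty, week_start = weeks,
        category = sample(c("NONE", "D0", "D1"), length(weeks),
                          replace = TRUE, prob = c(0.6, 0.25, 0.15))
      )
    }))
    for (i in seq_len(nrow(spells))) {
      wk <- spells$start_week[i] + 7 * (seq_len(spells$n_weeks[i]) - 1)
      cats <- rep("D2", spells$n_weeks[i])
      cats[ceiling(spells$n_weeks[i] / 2)] <- toupper(spells$peak[i])
      sel <- match(
        paste(spells$county[i], wk),
        paste(out$county, out$week_start)
      )
      out$category[sel] <- cats
    }
    arrange(out, .data$county, .data$week_start)
  })
}

#' Configuration for the synthetic indicator-table generator
#'
#' @param indicators Tibble with columns `indicator_id`, `county`, `tier`
#'   (the tier to embed: high/moderate/low), `direction`, `state_value`,
#'   `national_value` (references; `NA` when absent, but at least one per
#'   row).
#' @param offset Strictly positive displacement placed beyond the worst
#'   (or best) reference for embedded high (or low) tiers.
#' @param seed Integer random seed (places moderate values inside the open
#'   reference interval).
#' @return An `indicator_sim_config` object.
#' @export
indicator_sim_config <- function(indicators, offset = 2, seed = 1L) {
  stopifnot(offset > 0)
  req <- c("indicator_id", "county", "tier", "direction",
           "state_value", "national_value")
  missing_cols <- setdiff(req, names(indicators))
  if (length(missing_cols) > 0) {
    abort(paste("Missing indicator columns:", paste(missing_cols, collapse = ", ")))
  }
  if (!all(indicators$tier %in% c("high", "moderate", "low"))) {
    abort("Embedded tier must be high, moderate or low")
  }
  if (any(is.na(indicators$state_value) & is.na(indicators$national_value))) {
    abort("Each indicator row needs at least one reference value")
  }
  structure(list(indicators = indicators, offset = offset,
                 seed = as.integer(seed)),
            class = "indicator_sim_config")
}

#' Generate an indicator observation table with embedded tiers
#'
#' Each county value is displaced from its references in the direction
#' implied by its embedded tier: beyond the worst reference by `offset`
#' for high, beyond the best reference for low, and strictly between the
#' references (or tied with a sole/equal reference) for moderate — so
#' classification of the output recovers the embedded tier exactly.
#'
#' @param config An [indicator_sim_config()] object.
#' @return An observations tibble (`indicator_id`, `county`,
#'   `county_value`, `state_value`, `national_value`) with the embedded
#'   `true_tier` carried alongside.
#' @export
gen_indicator_table <- function(config) {
  stopifnot(inherits(config, "indicator_sim_config"))
  ind <- config$indicators
  withr::with_seed(config$seed, {
    vals <- vapply(seq_len(nrow(ind)), function(i) {
      refs <- c(ind$state_value[i], ind$national_value[i])
      refs <- refs[!is.na(refs)]
      sgn <- if (ind$direction[i] == "higher_is_worse") 1 else -1
      worst <- if (sgn == 1) max(refs) else min(refs)
      best <- if (sgn == 1) min(refs) else max(refs)
      switch(ind$tier[i],
        high = worst + sgn * config$offset,
        low = best - sgn * config$offset,
        moderate = {
          if (length(refs) < 2 || refs[1] == refs[2]) {
            refs[1] # tie with the sole (or equal) reference => moderate
          } else {
            lo <- min(refs); hi <- max(refs)
            lo + (hi - lo) * runif(1, 0.1, 0.9)
          }
        })
    }, double(1))
    tibble(
      indicator_id = ind$indicator_id, county = ind$county,
      county_value = vals,
      state_value = ind$state_value, national_value = ind$national_value,
      true_tier = ind$tier
    )
  })
}

#' Configuration for the synthetic claims generator
#'
#' @param counties Character vector of county identifiers.
#' @param start,end Dates bounding the record period.
#' @param background_rate Expected background records per county-day
#'   (Poisson; codes drawn from the distractor pool).
#' @param excess_rates Named numeric vector of expected extra records per
#'   county-day during exposure days, by hazard (e.g.
#'   `c(heat = 0.5, flood = 0.2)`).
#' @param code_pools Named list of per-hazard code pools plus a
#'   `background` pool; each pool is a tibble with `code` and
#'   `icd_version`. Defaults to the shipped reportable code sets plus
#'   common distractor codes.
#' @param seed Integer random seed.
#' @return A `claims_sim_config` object.
#' @export
claims_sim_config <- function(counties, start, end,
                              background_rate = 0.05,
                              excess_rates = c(heat = 0.5, flood = 0.2),
                              code_pools = default_code_pools(),
                              seed = 1L) {
  start <- as_date_strict(start, "start")
  end <- as_date_strict(end, "end")
  if (start > end) abort("date_range start must not be after end")
  if (background_rate < 0 || any(excess_rates < 0)) {
    abort("Rates must be >= 0")
  }
  for (hz in names(excess_rates)) {
    pool <- code_pools[[hz]]
    if (is.null(pool) || nrow(pool) == 0) {
      abort(paste0("Empty code pool for hazard ", hz))
    }
  }
  if (background_rate > 0 &&
      (is.null(code_pools$background) || nrow(code_pools$background) == 0)) {
    abort("Empty background code pool")
  }
  structure(list(counties = counties, start = start, end = end,
                 background_rate = background_rate,
                 excess_rates = excess_rates, code_pools = code_pools,
                 seed = as.integer(seed)),
            class = "claims_sim_config")
}

#' Default code pools for claims simulation
#'
#' Hazard pools are the shipped reportable code sets (with child
#' subdivisions for category-level codes); the background pool holds
#' distractor codes no hazard should match.
#'
#' @return Named list of tibbles with `code` and `icd_version`.
#' @export
default_code_pools <- function() {
  cs <- default_code_sets()
  pool_of <- function(s) {
    bind_rows(
      tibble(code = s$icd10, icd_version = 10L),
      tibble(code = s$icd9, icd_version = 9L)
    )
  }
  list(
    heat = pool_of(cs$heat),
    flood = pool_of(cs$flood),
    background = bind_rows(
      tibble(code = c("J18", "I10", "E119", "R51", "S525"), icd_version = 10L),
      tibble(code = c("486", "4019", "25000"), icd_version = 9L)
    )
  )
}

#' Generate synthetic ICD-coded health records
#'
#' Per county-day, draws a Poisson count of background records (distractor
#' codes) and, on hazard exposure days, an independent Poisson count of
#' excess records coded from that hazard's pool. Record counts are
#' independent across days (no within-person correlation).
#'
#' @param config A [claims_sim_config()] object.
#' @param exposure_days Tibble with columns `county`, `date`, `hazard`
#'   listing hazard-exposed county-days; `NULL` for none.
#' @return A health-records tibble (`record_id`, `county`, `date`,
#'   `icd_version`, `code`, `record_type`).
#' @export
gen_claims <- function(config, exposure_days = NULL) {
  stopifnot(inherits(config, "claims_sim_config"))
  exposure_days <- exposure_days %||%
    tibble(county = character(), date = as.Date(character()),
           hazard = character())
  exposure_days$date <- as_date_strict(exposure_days$date, "exposure day")
  withr::with_seed(config$seed, {
    dates <- seq(config$start, config$end, by = "day")
    draw <- function(n_each, pool, county, date) {
      total <- sum(n_each)
      if (total == 0) return(NULL)
      idx <- sample.int(nrow(pool), total, replace = TRUE)
      tibble(
        county = rep(county, n_each), date = rep(date, n_each),
        icd_version = pool$icd_version[idx], code = pool$code[idx],
        record_type = sample(c("death", "hospitalization", "ed_visit"),
                             total, replace = TRUE, prob = c(0.05, 0.35, 0.6))
      )
    }
    parts <- list()
    if (config$background_rate > 0) {
      grid <- tidyr::expand_grid(county = config$counties, date = dates)
      n_bg <- rpois(nrow(grid), config$background_rate)
      parts$bg <- draw(n_bg, config$code_pools$background, grid$county, grid$date)
    }
    for (hz in names(config$excess_rates)) {
      rate <- config$excess_rates[[hz]]
      exp_hz <- filter(exposure_days, .data$hazard == hz,
                       .data$county %in% config$counties,
                       .data$date >= config$start, .data$date <= config$end)
      if (rate > 0 && nrow(exp_hz) > 0) {
        n_ex <- rpois(nrow(exp_hz), rate)
        parts[[hz]] <- draw(n_ex, config$code_pools[[hz]], exp_hz$county,
                            exp_hz$date)
      }
    }
    out <- bind_rows(parts)
    if (is.null(out) || nrow(out) == 0) {
      return(tibble(record_id = character(), county = character(),
                    date = as.Date(character()), icd_version = integer(),
                    code = character(), record_type = character()))
    }
    out <- arrange(out, .data$county, .data$date, .data$code)
    out$record_id <- sprintf("R%05d", seq_len(nrow(out)))
    select(out, all_of(c("record_id", "county", "date", "icd_version",
                         "code", "record_type")))
  })
}
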