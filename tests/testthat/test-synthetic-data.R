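test_that("a flat sub-threshold baseline never reaches the heat threshold", {
  cfg <- weather_sim_config("A", "2012-05-01", "2012-09-30",
                            baseline_tmax_mean = 80, baseline_tmax_sd = 0)
  w <- gen_weather(cfg)
  expect_equal(nrow(w), as.integer(as.Date("2012-09-30") - as.Date("2012-05-01")) + 1)
  expect_true(all(w$tmax_f < 95))
})

test_that("embedded heat runs put exactly their days at or above the threshold", {
  cfg <- weather_sim_config("A", "2012-06-01", "2012-08-31",
                            baseline_tmax_mean = 80, baseline_tmax_sd = 0,
                            embedded_heat_runs = tibble::tibble(
                              county = "A", start = as.Date("2012-07-01"),
                              length = 3L, offset = 1))
  w <- gen_weather(cfg)
  expect_equal(sum(w$tmax_f >= 95), 3)
  expect_equal(w$date[w$tmax_f >= 95], as.Date("2012-07-01") + 0:2)
  expect_equal(unique(w$tmax_f[w$tmax_f >= 95]), 96)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- weather_sim_config(c("A", "B"), "2012-06-01", "2012-08-31", seed = 42)
  expect_identical(gen_weather(cfg), gen_weather(cfg))
  d1 <- gen_drought("A", "2012-01-02", "2012-12-31", seed = 42)
  expect_identical(d1, gen_drought("A", "2012-01-02", "2012-12-31", seed = 42))
  ccfg <- claims_sim_config("A", "2012-06-01", "2012-08-31", seed = 42)
  exp_days <- tibble::tibble(county = "A", date = as.Date("2012-07-01") + 0:9,
                             hazard = "heat")
  expect_identical(gen_claims(ccfg, exp_days), gen_claims(ccfg, exp_days))
  # a different seed changes the noise
  cfg2 <- weather_sim_config(c("A", "B"), "2012-06-01", "2012-08-31", seed = 43)
  expect_false(identical(gen_weather(cfg), gen_weather(cfg2)))
})

test_that("embedded runs outside the date range are configuration errors", {
  expect_error(
    weather_sim_config("A", "2012-06-01", "2012-06-30",
                       embedded_heat_runs = tibble::tibble(
                         county = "A", start = as.Date("2012-06-29"),
                         length = 5L, offset = 1)),
    "outside"
  )
  expect_error(
    weather_sim_config("A", "2012-06-01", "2012-06-30",
                       embedded_heat_runs = tibble::tibble(
                         county = "A", start = as.Date("2012-06-10"),
                         length = 0L, offset = 1)),
    ">= 1"
  )
})

test_that("noise-free recovery: embedded runs of 3+ days come back as events, 2-day runs only as annotations", {
  runs <- tibble::tibble(
    county = c("A", "A", "B"),
    start = as.Date(c("2012-06-10", "2012-07-20", "2012-07-21")),
    length = c(4L, 5L, 2L),
    offset = c(1, 2, 1)
  )
  cfg <- weather_sim_config(c("A", "B"), "2012-05-01", "2012-09-30",
                            baseline_tmax_mean = 80, baseline_tmax_sd = 0,
                            embedded_heat_runs = runs)
  w <- gen_weather(cfg)
  ev <- detect_heat_events(w)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$county, c("A", "A"))
  expect_equal(ev$start, runs$start[1:2])
  expect_equal(ev$duration_days, runs$length[1:2])
  # the 2-day run is never an event but surfaces as a near-threshold annotation
  dist <- consolidate_district_events(ev, heat_runs(w))
  i <- which(dist$start == as.Date("2012-07-20"))
  expect_equal(dist$near_threshold[[i]]$county, "B")
})

test_that("embedded drought spells are recovered exactly and quiet weeks stay below D2", {
  sp <- tibble::tibble(county = "A", start_week = as.Date("2012-06-04"),
                       n_weeks = 4L, peak = "D3")
  d <- gen_drought(c("A", "B"), "2012-01-02", "2012-12-31",
                   embedded_spells = sp, seed = 5)
  got <- extract_drought_spells(d)
  expect_equal(nrow(got), 1)
  expect_equal(got$county, "A")
  expect_equal(got$n_weeks, 4L)
  expect_equal(got$peak_category, "D3")
  # everything outside the embedded spell is below D2
  outside <- d[!(d$county == "A" & d$week_start >= sp$start_week &
                   d$week_start <= sp$start_week + 21), ]
  expect_true(all(drought_level(outside$category) < drought_level("D2")))
  expect_error(
    gen_drought("A", "2012-01-02", "2012-12-31",
                embedded_spells = tibble::tibble(
                  county = "A", start_week = as.Date("2012-06-04"),
                  n_weeks = 2L, peak = "D1")),
    "D2 or worse"
  )
})

test_that("indicator tables round-trip their embedded tiers through classification", {
  set.seed(99)
  reg <- default_registry()
  ids <- sample(reg$indicator_id, 30, replace = TRUE)
  ind <- tibble::tibble(
    indicator_id = ids,
    county = sample(green_river_counties(), 30, replace = TRUE),
    tier = sample(c("high", "moderate", "low"), 30, replace = TRUE),
    direction = reg$direction[match(ids, reg$indicator_id)],
    state_value = ifelse(runif(30) < 0.2, NA, rnorm(30, 12, 3)),
    national_value = rnorm(30, 12, 3)
  )
  ind <- ind[!duplicated(ind[c("indicator_id", "county")]), ]
  cfg <- indicator_sim_config(ind, offset = 2, seed = 11)
  obs <- gen_indicator_table(cfg)
  recovered <- vapply(seq_len(nrow(obs)), function(i) {
    classify_tier(obs$county_value[i], obs$state_value[i],
                  obs$national_value[i], ind$direction[i])
  }, character(1))
  expect_equal(recovered, obs$true_tier)

  # construction example: high, higher-is-worse, refs 10 and 8, offset 2 -> 12
  one <- indicator_sim_config(tibble::tibble(
    indicator_id = "elderly", county = "A", tier = "high",
    direction = "higher_is_worse", state_value = 10, national_value = 8),
    offset = 2)
  expect_equal(gen_indicator_table(one)$county_value, 12)
  # low, higher-is-worse: below both references
  lo <- indicator_sim_config(tibble::tibble(
    indicator_id = "elderly", county = "A", tier = "low",
    direction = "higher_is_worse", state_value = 10, national_value = 8),
    offset = 2)
  expect_lt(gen_indicator_table(lo)$county_value, 8)
})

test_that("claims generation respects rates, pools and exposure days", {
  # zero rates produce no records
  cfg0 <- claims_sim_config("A", "2012-06-01", "2012-08-31",
                            background_rate = 0, excess_rates = c(heat = 0))
  expect_equal(nrow(gen_claims(cfg0)), 0)

  # heat excess only: every record uses a heat-pool code on an exposure day
  exp_days <- tibble::tibble(county = "A", date = as.Date("2012-07-01") + 0:19,
                             hazard = "heat")
  cfg <- claims_sim_config("A", "2012-06-01", "2012-08-31",
                           background_rate = 0, excess_rates = c(heat = 1.5),
                           seed = 3)
  recs <- gen_claims(cfg, exp_days)
  expect_gt(nrow(recs), 0)
  pools <- default_code_pools()
  expect_true(all(recs$code %in% normalize_icd(pools$heat$code)))
  expect_true(all(recs$date %in% exp_days$date))

  # Poisson mean: counts over 20 seeds stay within 3 sd of rate x days
  n_days <- nrow(exp_days)
  rate <- 1.5
  counts <- vapply(1:20, function(s) {
    c2 <- claims_sim_config("A", "2012-06-01", "2012-08-31",
                            background_rate = 0, excess_rates = c(heat = rate),
                            seed = s)
    nrow(gen_claims(c2, exp_days))
  }, double(1))
  mu <- rate * n_days
  expect_lt(abs(mean(counts) - mu), 3 * sqrt(mu / 20))

  # empty pool is a configuration error
  expect_error(
    claims_sim_config("A", "2012-06-01", "2012-06-30",
                      excess_rates = c(heat = 1),
                      code_pools = list(heat = tibble::tibble(
                        code = character(), icd_version = integer()),
                        background = default_code_pools()$background)),
    "Empty code pool"
  )
})
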