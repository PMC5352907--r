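# Independent brute-force oracles used to cross-check the run-length
# algorithms. These deliberately enumerate rather than scan with rle, so
# they share no code path with the implementation.

md_in_season <- function(dates, season = c("05-01", "09-30")) {
  md <- format(dates, "%m-%d")
  md >= season[1] & md <= season[2]
}

# Exhaustive-window heat-event oracle: tests every (start, end) window of a
# complete daily grid for all-qualifying days, minimum length, and
# non-extendability.
oracle_heat_events <- function(dates, tmax, threshold = 95, min_run = 3,
                               season = c("05-01", "09-30")) {
  n <- length(dates)
  q <- !is.na(tmax) & tmax >= threshold & md_in_season(dates, season)
  if (n == 0 || !any(q)) {
    return(data.frame(start = as.Date(character()), end = as.Date(character())))
  }
  S <- c(0, cumsum(q))
  i <- rep(seq_len(n), times = n)
  j <- rep(seq_len(n), each = n)
  len <- j - i + 1
  allq <- (S[j + 1] - S[i]) == len
  left_ok <- i == 1 | !q[pmax(i - 1, 1)]
  right_ok <- j == n | !q[pmin(j + 1, n)]
  keep <- len >= min_run & allq & left_ok & right_ok
  out <- data.frame(start = dates[i[keep]], end = dates[j[keep]])
  out[order(out$start), , drop = FALSE]
}

# Week-scan drought-spell oracle: walks the weekly series one week at a
# time, opening and closing spells by hand.
oracle_drought_spells <- function(week_start, category, min_severity = "D2") {
  scale <- c("NONE", "D0", "D1", "D2", "D3", "D4")
  lev <- match(toupper(category), scale) - 1
  min_lev <- match(toupper(min_severity), scale) - 1
  spells <- list()
  open <- FALSE
  for (k in seq_along(week_start)) {
    consecutive <- k > 1 && as.numeric(week_start[k] - week_start[k - 1]) == 7
    if (open && !consecutive) {
      open <- FALSE
    }
    if (lev[k] >= min_lev) {
      if (open) {
        cur <- spells[[length(spells)]]
        cur$end_week <- week_start[k]
        cur$n_weeks <- cur$n_weeks + 1L
        cur$peak <- max(cur$peak, lev[k])
        spells[[length(spells)]] <- cur
      } else {
        spells[[length(spells) + 1]] <- list(start_week = week_start[k],
                                             end_week = week_start[k],
                                             n_weeks = 1L, peak = lev[k])
        open <- TRUE
      }
    } else {
      open <- FALSE
    }
  }
  if (length(spells) == 0) {
    return(data.frame(start_week = as.Date(character()),
                      end_week = as.Date(character()),
                      n_weeks = integer(), peak_category = character()))
  }
  data.frame(
    start_week = as.Date(vapply(spells, function(s) as.character(s$start_week), "")),
    end_week = as.Date(vapply(spells, function(s) as.character(s$end_week), "")),
    n_weeks = vapply(spells, function(s) s$n_weeks, integer(1)),
    peak_category = scale[vapply(spells, function(s) s$peak, double(1)) + 1]
  )
}

# Day-by-day overlap oracle: walks every calendar day in the union of the
# event spans and the window and counts it by hand.
oracle_overlap <- function(events, window,
                           policy = c("containment", "intersection")) {
  policy <- match.arg(policy)
  if (nrow(events) == 0) return(0L)
  win <- seq(window[1], window[2], by = "day")
  count <- 0L
  all_days <- seq(min(events$start), max(events$end), by = "day")
  for (d in as.list(all_days)) {
    if (!d %in% win) next
    covered <- FALSE
    for (i in seq_len(nrow(events))) {
      inside_event <- d >= events$start[i] && d <= events$end[i]
      if (!inside_event) next
      if (policy == "containment") {
        if (events$start[i] >= window[1] && events$end[i] <= window[2]) covered <- TRUE
      } else {
        covered <- TRUE
      }
    }
    if (covered) count <- count + 1L
  }
  count
}

# Random single-county weather series on a complete daily grid, with
# temperatures hovering around the heat threshold so runs of every length
# occur. Dates sit inside one summer so the season window is exercised at
# its edges.
random_weather <- function(seed, n_days = NULL, county = "A") {
  set.seed(seed)
  n <- n_days %||% sample(30:400, 1)
  start <- as.Date("2010-04-01") + sample(0:60, 1)
  dates <- seq(start, by = "day", length.out = n)
  tmax <- rnorm(n, mean = 93, sd = 4)
  tmax[sample(n, size = floor(n * 0.05))] <- NA # missing observations
  tibble::tibble(county = county, date = dates, tmax_f = tmax,
                 precip_in = ifelse(runif(n) < 0.3, rexp(n, 2), 0))
}

random_drought <- function(seed, n_weeks = NULL, county = "A") {
  set.seed(seed + 10000)
  n <- n_weeks %||% sample(10:60, 1)
  scale <- c("NONE", "D0", "D1", "D2", "D3", "D4")
  tibble::tibble(
    county = county,
    week_start = as.Date("2011-01-03") + 7 * (seq_len(n) - 1),
    category = sample(scale, n, replace = TRUE,
                      prob = c(0.3, 0.15, 0.15, 0.2, 0.12, 0.08))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
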