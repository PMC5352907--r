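#' The seven Green River District counties
#'
#' @return Character vector of the seven county names, in the order the
#'   district's reports print them.
#' @export
green_river_counties <- function() {
  c("Daviess", "Hancock", "Henderson", "McLean", "Ohio", "Union", "Webster")
}

#' Transcribed district extreme-heat event record, 2000-2012
#'
#' The district's published record of dates on which one or more county met
#' the extreme heat exposure definition (three or more consecutive days at
#' or above 95 degF, May-September), with the counties affected by each
#' window and the footnoted near-threshold annotations (counties that
#' reached the threshold for only two days during a window).
#'
#' @return A tibble with columns `start`, `end` (Date),
#'   `counties_affected` and `near_threshold` (lists of character
#'   vectors), `duration_days`, and `note`.
#' @export
#' @examples
#' ev <- green_river_heat_events()
#' range(ev$duration_days)
green_river_heat_events <- function() {
  path <- system.file("extdata", "green_river_heat_events.csv",
                      package = "climvuln", mustWork = TRUE)
  df <- readr::read_csv(path, col_types = readr::cols(
    start = readr::col_date(), end = readr::col_date(),
    counties = readr::col_character(),
    near_threshold = readr::col_character(),
    note = readr::col_character()
  ))
  split_list <- function(x) {
    lapply(x, function(s) if (is.na(s) || s == "") character() else strsplit(s, ";")[[1]])
  }
  tibble(
    start = df$start,
    end = df$end,
    counties_affected = split_list(df$counties),
    near_threshold = split_list(df$near_threshold),
    duration_days = as.integer(df$end - df$start + 1),
    note = df$note
  )
}

#' Transcribed district high-vulnerability matrix
#'
#' The district's published county-by-indicator-by-hazard table of high
#' vulnerability flags, in long form: one row per printed checkmark. Used
#' as a regression fixture independent of the classification module.
#'
#' @return A tibble with columns `county`, `indicator_id`, `hazard`, and
#'   `tier` (all `"high"`).
#' @export
green_river_high_vulnerability <- function() {
  path <- system.file("extdata", "green_river_high_vulnerability.csv",
                      package = "climvuln", mustWork = TRUE)
  df <- readr::read_csv(path, col_types = readr::cols(
    county = readr::col_character(),
    indicator_id = readr::col_character(),
    hazard = readr::col_character()
  ))
  df$tier <- "high"
  df
}

#' The district high-vulnerability matrix as a hazard_matrix object
#'
#' Builds a [build_matrix()] object directly from the transcribed fixture,
#' keeping per-hazard flags exactly as printed (no fan-out: the fixture
#' stores hazard-specific checkmarks, not indicator-level tiers).
#'
#' @return A `hazard_matrix` covering the seven district counties.
#' @export
green_river_matrix <- function() {
  fx <- green_river_high_vulnerability()
  reg <- default_registry()
  # validate hazards against the registry, then install entries as printed
  m <- build_matrix(tibble(indicator_id = character(), county = character(),
                           tier = character()),
                    registry = reg, counties = green_river_counties())
  pairs_ok <- vapply(seq_len(nrow(fx)), function(i) {
    j <- match(fx$indicator_id[i], reg$indicator_id)
    !is.na(j) && fx$hazard[i] %in% reg$hazards[[j]]
  }, logical(1))
  if (!all(pairs_ok)) {
    stop_stage("fixture", "Fixture entry with an (indicator, hazard) pair absent from the registry")
  }
  m$entries <- arrange(
    select(fx, all_of(c("county", "indicator_id", "hazard", "tier"))),
    .data$county, .data$indicator_id, .data$hazard
  )
  m
}
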