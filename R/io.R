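#' Read a daily weather CSV
#'
#' Expects columns `date` (ISO-8601), `county`, `tmax_f`, `precip_in`; an
#' empty cell is a missing observation. Temperatures are degrees Fahrenheit
#' and precipitation inches; no implicit unit conversion is performed.
#'
#' @param path Path to the CSV file.
#' @param units Temperature units declared for the file; only `"F"` is
#'   supported and a mismatch is an error.
#' @return A tibble with columns `county`, `date` (Date), `tmax_f`,
#'   `precip_in`, sorted by county and date, carrying a `temp_units`
#'   attribute.
#' @export
read_weather_csv <- function(path, units = "F") {
  if (!identical(units, "F")) {
    abort("Temperature units must be \"F\"; convert the file before reading")
  }
  df <- readr::read_csv(path, col_types = readr::cols(
    date = readr::col_date(),
    county = readr::col_character(),
    tmax_f = readr::col_double(),
    precip_in = readr::col_double()
  ))
  out <- arrange(select(df, all_of(c("county", "date", "tmax_f", "precip_in"))),
                 .data$county, .data$date)
  attr(out, "temp_units") <- "F"
  validate_weather(out)
  out
}

#' Write a daily weather CSV
#'
#' @param weather Weather tibble (see [read_weather_csv()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_weather_csv <- function(weather, path) {
  readr::write_csv(select(weather, all_of(c("date", "county", "tmax_f", "precip_in"))), path, na = "")
  invisible(path)
}

#' Read a weekly drought-category CSV
#'
#' Expects columns `week_start` (ISO-8601), `county`, `category` in
#' `NONE, D0, D1, D2, D3, D4`.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `county`, `week_start` (Date), `category`,
#'   sorted by county and week.
#' @export
read_drought_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    week_start = readr::col_date(),
    county = readr::col_character(),
    category = readr::col_character()
  ))
  df$category <- toupper(df$category)
  drought_level(df$category) # validates
  arrange(select(df, all_of(c("county", "week_start", "category"))),
          .data$county, .data$week_start)
}

#' Write a weekly drought-category CSV
#' @param drought Drought tibble (see [read_drought_csv()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_drought_csv <- function(drought, path) {
  readr::write_csv(select(drought, all_of(c("week_start", "county", "category"))), path, na = "")
  invisible(path)
}

#' Read an indicator observations CSV
#'
#' Expects columns `indicator_id`, `county`, `county_value`, `state_value`,
#' `national_value`; empty reference cells mean the reference is absent.
#'
#' @param path Path to the CSV file.
#' @return A tibble of observations.
#' @export
read_observations_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    indicator_id = readr::col_character(),
    county = readr::col_character(),
    county_value = readr::col_double(),
    state_value = readr::col_double(),
    national_value = readr::col_double()
  ))
}

#' Write an indicator observations CSV
#' @param observations Observations tibble (see [read_observations_csv()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations_csv <- function(observations, path) {
  readr::write_csv(observations, path, na = "")
  invisible(path)
}

#' Read an ICD-coded health records CSV
#'
#' Expects columns `record_id`, `county`, `date` (ISO-8601), `icd_version`
#' (9 or 10), `code`, `record_type` (`death`, `hospitalization`, `ed_visit`).
#'
#' @param path Path to the CSV file.
#' @return A tibble of health records with normalized codes.
#' @export
read_records_csv <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    record_id = readr::col_character(),
    county = readr::col_character(),
    date = readr::col_date(),
    icd_version = readr::col_integer(),
    code = readr::col_character(),
    record_type = readr::col_character()
  ))
  df$code <- normalize_icd(df$code)
  df
}

#' Write an ICD-coded health records CSV
#' @param records Records tibble (see [read_records_csv()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  readr::write_csv(records, path, na = "")
  invisible(path)
}
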