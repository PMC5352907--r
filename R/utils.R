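#' @importFrom rlang %||% abort .data
#' @importFrom dplyr arrange bind_rows distinct filter group_by left_join mutate
#'   n pull rename row_number select summarise ungroup all_of across
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm rpois rbinom runif
NULL

# Ordered US Drought Monitor scale; NONE = no declaration.
DROUGHT_CATEGORIES <- c("NONE", "D0", "D1", "D2", "D3", "D4")

HAZARDS <- c("heat", "drought", "flood")

TIERS <- c("high", "moderate", "low", "unknown")

#' Numeric severity level of a US Drought Monitor category
#'
#' Maps the ordinal drought scale to integers: NONE = 0, D0 = 1, ... D4 = 5,
#' so that "at or above D2" comparisons are simple numeric ones.
#'
#' @param category Character vector of categories in
#'   `c("NONE", "D0", "D1", "D2", "D3", "D4")` (case-insensitive).
#' @return Integer vector of the same length.
#' @export
#' @examples
#' drought_level(c("NONE", "D2", "D4"))
drought_level <- function(category) {
  category <- toupper(as.character(category))
  bad <- !category %in% DROUGHT_CATEGORIES & !is.na(category)
  if (any(bad)) {
    abort(paste0(
      "Invalid drought category: ",
      paste(unique(category[bad]), collapse = ", "),
      " (expected one of ", paste(DROUGHT_CATEGORIES, collapse = ", "), ")"
    ))
  }
  match(category, DROUGHT_CATEGORIES) - 1L
}

# TRUE for dates whose month-day falls inside [season[1], season[2]].
# season is c("mm-dd", "mm-dd"), non-wrapping within a year.
in_season <- function(dates, season) {
  md <- format(dates, "%m-%d")
  md >= season[1] & md <= season[2]
}

as_date_strict <- function(x, what = "date") {
  if (inherits(x, "Date")) return(x)
  out <- tryCatch(as.Date(x), error = function(e) NA)
  if (anyNA(out) && !anyNA(x)) {
    abort(paste0("Could not parse ", what, " values as ISO-8601 dates"))
  }
  out
}

# Maximal runs of TRUE in a logical vector; returns tibble(start_idx, end_idx, length)
true_runs <- function(q) {
  q[is.na(q)] <- FALSE
  r <- rle(q)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(
    start_idx = starts[keep],
    end_idx = ends[keep],
    length = r$lengths[keep]
  )
}

#' Normalize an ICD code string
#'
#' Uppercases and strips dots and whitespace, so `"x30"`, `"X30"` and
#' `"X30."` all normalize to `"X30"` and `"E900.0"` to `"E9000"`.
#'
#' @param code Character vector of ICD-9 or ICD-10 codes.
#' @return Character vector of normalized codes.
#' @export
normalize_icd <- function(code) {
  gsub("[.[:space:]]", "", toupper(as.character(code)))
}

stop_stage <- function(stage, msg) {
  abort(paste0("[", stage, "] ", msg))
}
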