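#' Assemble the county-by-indicator-by-hazard vulnerability matrix
#'
#' Fans each classified (indicator, county) tier out to exactly the hazards
#' the registry lists for that indicator, producing the long-form matrix of
#' tiers behind the district's "high vulnerability by climate hazard"
#' table. Counties with no high entries still appear in the county list.
#'
#' @param tiers A tibble with columns `indicator_id`, `county`, `tier`
#'   (from [classify_table()], or transcribed directly).
#' @param registry A registry tibble (see [default_registry()]).
#' @param counties Optional ordered character vector of counties the matrix
#'   should cover; defaults to the counties present in `tiers`.
#' @return A `hazard_matrix` object: a list with `entries` (tibble
#'   `county`, `indicator_id`, `hazard`, `tier`), `counties` and
#'   `registry`.
#' @export
build_matrix <- function(tiers, registry = default_registry(),
                         counties = NULL) {
  validate_registry(registry)
  counties <- counties %||% sort(unique(tiers$county))
  if (nrow(tiers) > 0) {
    unknown <- setdiff(unique(tiers$indicator_id), registry$indicator_id)
    if (length(unknown) > 0) {
      stop_stage("matrix", paste("Tier rows reference indicators absent from the registry:",
                                 paste(sort(unknown), collapse = ", ")))
    }
    if (!all(tiers$tier %in% TIERS)) {
      stop_stage("matrix", "Invalid tier value")
    }
    hazard_map <- tibble(
      indicator_id = rep(registry$indicator_id, lengths(registry$hazards)),
      hazard = unlist(registry$hazards)
    )
    entries <- left_join(
      select(tiers, all_of(c("indicator_id", "county", "tier"))),
      hazard_map, by = "indicator_id", relationship = "many-to-many"
    )
    entries <- distinct(arrange(
      select(entries, all_of(c("county", "indicator_id", "hazard", "tier"))),
      .data$county, .data$indicator_id, .data$hazard
    ))
  } else {
    entries <- tibble(county = character(), indicator_id = character(),
                      hazard = character(), tier = character())
  }
  structure(
    list(entries = entries, counties = counties, registry = registry),
    class = "hazard_matrix"
  )
}

#' @export
print.hazard_matrix <- function(x, ...) {
  n_high <- sum(x$entries$tier == "high")
  cat("Hazard x indicator vulnerability matrix\n")
  cat(sprintf("  counties   : %s\n", paste(x$counties, collapse = ", ")))
  cat(sprintf("  entries    : %d (high: %d)\n", nrow(x$entries), n_high))
  invisible(x)
}

#' Count distinct high-vulnerability indicators for a county
#'
#' Counts distinct indicators classified high for the county under at least
#' one hazard — distinct indicators, not indicator-hazard checkmarks, which
#' is the reading under which the district matrix yields six to eight per
#' county.
#'
#' @param matrix A `hazard_matrix` from [build_matrix()].
#' @param county County identifier.
#' @return Integer count.
#' @export
count_high <- function(matrix, county) {
  stopifnot(inherits(matrix, "hazard_matrix"))
  if (!county %in% matrix$counties) {
    stop_stage("matrix", paste0("Unknown county: ", county))
  }
  e <- matrix$entries
  length(unique(e$indicator_id[e$county == county & e$tier == "high"]))
}

#' Count counties flagged high for an indicator under a hazard
#'
#' @param matrix A `hazard_matrix` from [build_matrix()].
#' @param indicator_id Indicator identifier (must be in the registry).
#' @param hazard One of `"heat"`, `"drought"`, `"flood"`; must be among the
#'   hazards the registry maps the indicator to.
#' @return Integer count of counties.
#' @export
count_counties_flagged <- function(matrix, indicator_id, hazard) {
  stopifnot(inherits(matrix, "hazard_matrix"))
  i <- match(indicator_id, matrix$registry$indicator_id)
  if (is.na(i)) stop_stage("matrix", paste0("Unknown indicator: ", indicator_id))
  if (!hazard %in% matrix$registry$hazards[[i]]) {
    stop_stage("matrix", paste0("Hazard \"", hazard, "\" is not mapped to indicator ",
                                indicator_id, " in the registry"))
  }
  e <- matrix$entries
  length(unique(e$county[e$indicator_id == indicator_id &
                           e$hazard == hazard & e$tier == "high"]))
}

#' Summarize a hazard matrix
#'
#' @param matrix A `hazard_matrix` from [build_matrix()].
#' @return A list with `per_county` (tibble `county`, `n_high` of distinct
#'   high indicators), `per_indicator_hazard` (tibble `indicator_id`,
#'   `hazard`, `n_counties` flagged high), and `min_high` / `max_high`
#'   across counties. Ordering follows the matrix county order and
#'   registry indicator order, so reports diff cleanly.
#' @export
matrix_summary <- function(matrix) {
  stopifnot(inherits(matrix, "hazard_matrix"))
  per_county <- tibble(
    county = matrix$counties,
    n_high = vapply(matrix$counties, function(cty) count_high(matrix, cty),
                    integer(1), USE.NAMES = FALSE)
  )
  e <- filter(matrix$entries, .data$tier == "high")
  pairs <- distinct(select(e, all_of(c("indicator_id", "hazard"))))
  if (nrow(pairs) > 0) {
    per_ih <- summarise(group_by(e, .data$indicator_id, .data$hazard),
                        n_counties = length(unique(.data$county)),
                        .groups = "drop")
    ord <- match(per_ih$indicator_id, matrix$registry$indicator_id)
    per_ih <- per_ih[order(ord, match(per_ih$hazard, HAZARDS)), ]
  } else {
    per_ih <- tibble(indicator_id = character(), hazard = character(),
                     n_counties = integer())
  }
  list(
    per_county = per_county,
    per_indicator_hazard = per_ih,
    min_high = if (nrow(per_county) > 0) min(per_county$n_high) else 0L,
    max_high = if (nrow(per_county) > 0) max(per_county$n_high) else 0L
  )
}
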