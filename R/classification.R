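#' The default indicator registry
#'
#' Loads the shipped registry of climate-and-health indicators: identifier,
#' display name, category (environmental exposure, health outcome,
#' population vulnerability, environmental vulnerability), the hazards each
#' indicator informs (heat, drought, flood), the direction in which larger
#' values are worse, and, for the five standard-compared indicators
#' (fine-particulate air pollution, obesity, heart-disease mortality,
#' asthma hospitalizations, cerebrovascular deaths), the federal benchmark
#' source. Standard values are deliberately left unset: they are policy
#' inputs the user supplies via [set_standard()] or a registry YAML.
#'
#' @param path Optional path to a registry YAML; defaults to the file
#'   shipped with the package.
#' @return A registry tibble with columns `indicator_id`, `name`,
#'   `category`, `hazards` (list of character vectors), `direction`,
#'   `standard_source`, `standard_value`.
#' @export
#' @examples
#' reg <- default_registry()
#' reg[reg$indicator_id == "air_pollution_pm25", ]
default_registry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "indicator_registry.yaml",
                                package = "climvuln", mustWork = TRUE)
  read_registry(path)
}

#' Read an indicator registry YAML
#'
#' @param path Path to a YAML file whose `indicators` entry is a list of
#'   records with `id`, `name`, `category`, `hazards`, `direction` and an
#'   optional `standard` block (`source`, `value`).
#' @return A registry tibble (see [default_registry()]).
#' @export
read_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  recs <- raw$indicators %||% raw
  reg <- bind_rows(lapply(recs, function(r) {
    tibble(
      indicator_id = r$id,
      name = r$name %||% r$id,
      category = r$category,
      hazards = list(unlist(r$hazards)),
      direction = r$direction,
      standard_source = r$standard$source %||% NA_character_,
      standard_value = as.numeric(r$standard$value %||% NA_real_)
    )
  }))
  validate_registry(reg)
  reg
}

validate_registry <- function(reg, stage = "registry") {
  categories <- c("environmental_exposure", "health_outcome",
                  "population_vulnerability", "environmental_vulnerability")
  if (anyDuplicated(reg$indicator_id)) {
    stop_stage(stage, "Duplicate indicator ids")
  }
  if (!all(reg$category %in% categories)) {
    stop_stage(stage, "Invalid indicator category")
  }
  if (!all(reg$direction %in% c("higher_is_worse", "lower_is_worse"))) {
    stop_stage(stage, "direction must be higher_is_worse or lower_is_worse")
  }
  hz_ok <- vapply(reg$hazards, function(h) {
    length(h) > 0 && all(h %in% HAZARDS)
  }, logical(1))
  if (!all(hz_ok)) {
    stop_stage(stage, "Every indicator needs a non-empty hazard set from heat/drought/flood")
  }
  invisible(reg)
}

#' Set a federal-standard value on a registry
#'
#' @param registry A registry tibble.
#' @param indicator_id Indicator to update.
#' @param value Numeric benchmark value in the indicator's own units.
#' @param source Optional source label; kept if already present.
#' @return The updated registry.
#' @export
set_standard <- function(registry, indicator_id, value, source = NULL) {
  i <- match(indicator_id, registry$indicator_id)
  if (is.na(i)) abort(paste0("Unknown indicator id: ", indicator_id))
  registry$standard_value[i] <- as.numeric(value)
  if (!is.null(source)) registry$standard_source[i] <- source
  registry
}

# signed "badness": positive when value is on the worse side of ref
worse_by <- function(value, ref, direction) {
  if (direction == "higher_is_worse") value - ref else ref - value
}

#' Classify one indicator observation into a vulnerability tier
#'
#' Compares a county value against its state and national references under
#' the indicator's direction. With both references available the county is
#' `high` when strictly worse than both, `low` when strictly better than
#' both, and `moderate` otherwise (between them, or tied with either).
#' With a single reference: strictly worse is `high`, strictly better is
#' `low`, a tie is `moderate`. With no reference the tier is `unknown`.
#'
#' @param county_value Numeric county value (pre-normalized rate,
#'   percentage or concentration).
#' @param state_value,national_value Reference values; `NA` when absent.
#' @param direction `"higher_is_worse"` or `"lower_is_worse"`.
#' @return One of `"high"`, `"moderate"`, `"low"`, `"unknown"`.
#' @export
#' @examples
#' # district PM2.5 vs state and national annual means
#' classify_tier(14.1, 13.5, 11.1, "higher_is_worse")
#' # floodplain population share vs the state share only
#' classify_tier(13.6, 5.4, NA, "higher_is_worse")
classify_tier <- function(county_value, state_value = NA, national_value = NA,
                          direction = "higher_is_worse") {
  if (!is.finite(county_value)) {
    abort("County value must be finite")
  }
  direction <- match.arg(direction, c("higher_is_worse", "lower_is_worse"))
  refs <- c(state_value, national_value)
  refs <- refs[!is.na(refs)]
  if (length(refs) == 0) return("unknown")
  deltas <- vapply(refs, function(r) worse_by(county_value, r, direction), double(1))
  if (all(deltas > 0)) return("high")
  if (all(deltas < 0)) return("low")
  "moderate"
}

#' Compare an observation with its federal standard
#'
#' The five standard-compared indicators carry a configured benchmark; a
#' county value strictly on the worse side of the benchmark `fails` it,
#' ties `meet` it, and indicators without a configured standard are
#' `not_applicable`. Standards supplement the state/national tier
#' classification; they never replace it.
#'
#' @param county_value Numeric county value.
#' @param defn One registry row (a one-row tibble or list with `direction`,
#'   `standard_source`, `standard_value`).
#' @return One of `"meets"`, `"fails"`, `"not_applicable"`.
#' @export
compare_to_standard <- function(county_value, defn) {
  src <- defn$standard_source
  val <- defn$standard_value
  if ((is.na(src) || is.null(src)) && is.na(val)) return("not_applicable")
  if (is.na(val)) {
    abort(paste0("Standard \"", src, "\" is configured without a value; ",
                 "supply one with set_standard()"))
  }
  if (worse_by(county_value, val, defn$direction) > 0) "fails" else "meets"
}

#' Classify a table of indicator observations
#'
#' Applies [classify_tier()] and [compare_to_standard()] to every
#' observation, using the registry for direction and standards. The result
#' is deterministic and independent of input row order.
#'
#' @param observations Tibble with columns `indicator_id`, `county`,
#'   `county_value`, `state_value`, `national_value`.
#' @param registry A registry tibble (see [default_registry()]).
#' @return A tibble with columns `indicator_id`, `county`, `tier`,
#'   `standard_result`, sorted by indicator then county.
#' @export
classify_table <- function(observations, registry = default_registry()) {
  validate_registry(registry)
  if (nrow(observations) == 0) {
    return(tibble(indicator_id = character(), county = character(),
                  tier = character(), standard_result = character()))
  }
  unknown <- setdiff(unique(observations$indicator_id), registry$indicator_id)
  if (length(unknown) > 0) {
    stop_stage("classify", paste("Unknown indicator ids:",
                                 paste(sort(unknown), collapse = ", ")))
  }
  obs <- left_join(observations,
                   select(registry, all_of(c("indicator_id", "direction",
                                             "standard_source", "standard_value"))),
                   by = "indicator_id")
  out <- tibble(
    indicator_id = obs$indicator_id,
    county = obs$county,
    tier = vapply(seq_len(nrow(obs)), function(i) {
      classify_tier(obs$county_value[i], obs$state_value[i],
                    obs$national_value[i], obs$direction[i])
    }, character(1)),
    standard_result = vapply(seq_len(nrow(obs)), function(i) {
      compare_to_standard(obs$county_value[i], obs[i, ])
    }, character(1))
  )
  arrange(out, .data$indicator_id, .data$county)
}
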