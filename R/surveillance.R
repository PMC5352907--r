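#' Default reportable-outcome ICD code sets
#'
#' Loads the shipped per-hazard code sets: heat-related deaths (ICD-10 X30)
#' and heat stress hospitalizations / emergency department visits (ICD-9
#' 992, E900.0, E900.9) restricted to May-September; unintentional
#' drowning deaths (ICD-10 W69, W70, X38) and flooding-related morbidity
#' (ICD-9 E908.2, E908.9, E910.8, E910.9) year-round. The drought outcome
#' set is in development and ships empty; the drought exposure trigger is
#' active regardless.
#'
#' @param path Optional path to a code-set YAML; defaults to the file
#'   shipped with the package.
#' @return A named list (by hazard) of lists with elements `icd10`,
#'   `icd9` (normalized code vectors) and `season` (two `"mm-dd"` strings
#'   or `NULL`).
#' @export
#' @examples
#' default_code_sets()$heat
default_code_sets <- function(path = NULL) {
  path <- path %||% system.file("extdata", "surveillance_code_sets.yaml",
                                package = "climvuln", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  sets <- raw$code_sets %||% raw
  out <- lapply(sets, function(s) {
    list(
      icd10 = normalize_icd(unlist(s$icd10) %||% character()),
      icd9 = normalize_icd(unlist(s$icd9) %||% character()),
      season = if (is.null(s$season)) NULL else as.character(unlist(s$season))
    )
  })
  for (hz in names(out)) {
    if (!hz %in% HAZARDS) abort(paste0("Unknown hazard in code sets: ", hz))
  }
  out
}

# ICD syntax checks on normalized (dot-free, uppercase) codes.
# ICD-9: 3-5 digits, or E + 3-4 digits, or V + 2-4 digits.
# ICD-10: letter + 2 alphanumerics, optionally up to 4 more.
icd_code_ok <- function(code, version) {
  ifelse(
    version == 9,
    grepl("^[0-9]{3,5}$", code) | grepl("^E[0-9]{3,4}$", code) |
      grepl("^V[0-9]{2,4}$", code),
    version == 10 & grepl("^[A-Z][0-9][0-9A-Z]([0-9A-Z]{1,4})?$", code)
  )
}

# A record code matches a listed category code when it equals it or extends
# it as a child subdivision (prefix match on normalized codes): X30, X300
# match a listed X30; X3 does not.
code_matches <- function(code, listed) {
  if (length(listed) == 0) return(rep(FALSE, length(code)))
  Reduce(`|`, lapply(listed, function(l) {
    code == l | startsWith(code, l)
  }))
}

#' Match health records against reportable-outcome code sets
#'
#' A record matches a hazard when its normalized ICD code (uppercased,
#' dots removed) equals one of the hazard's listed codes for its ICD
#' version, or extends a listed category code as a child subdivision.
#' Hazards with a seasonal window (heat: May-September by default) only
#' match records dated inside the window. Malformed codes are rejected
#' with a reason, never silently dropped.
#'
#' @param records Health records tibble (`record_id`, `county`, `date`,
#'   `icd_version`, `code`, `record_type`).
#' @param code_sets Per-hazard code sets (see [default_code_sets()]).
#' @return A list with one tibble of matched records per hazard and a
#'   `rejected` tibble (`record_id`, `code`, `reason`).
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   record_id = c("r1", "r2"), county = "Union",
#'   date = as.Date(c("2012-07-15", "2012-01-10")),
#'   icd_version = 10L, code = c("X30", "X30"),
#'   record_type = "death")
#' m <- match_reportable(recs)
#' m$heat$record_id  # only the July record matches
match_reportable <- function(records, code_sets = default_code_sets()) {
  records$code <- normalize_icd(records$code)
  ok <- icd_code_ok(records$code, records$icd_version)
  rejected <- tibble(
    record_id = records$record_id[!ok],
    code = records$code[!ok],
    reason = paste0("Malformed ICD-", records$icd_version[!ok], " code")
  )
  if (nrow(rejected) > 0) {
    message(nrow(rejected), " record(s) rejected for malformed codes")
  }
  good <- records[ok, , drop = FALSE]
  out <- lapply(code_sets, function(cs) {
    hit <- ifelse(good$icd_version == 10,
                  code_matches(good$code, cs$icd10),
                  code_matches(good$code, cs$icd9))
    if (!is.null(cs$season)) {
      hit <- hit & in_season(good$date, cs$season)
    }
    good[hit, , drop = FALSE]
  })
  out$rejected <- rejected
  out
}

#' Evaluate surveillance triggers on environmental series
#'
#' Emits exposure alerts per the proposed surveillance rules: a heat alert
#' for each county on the third qualifying day (at or above the heat
#' threshold, in season) of a consecutive run and on each of the run's
#' subsequent days; a drought alert for each county-week declared at D2 or
#' worse; a flood alert for each county-day with precipitation strictly
#' over the threshold. Alerts are deterministic and idempotent.
#'
#' @param weather Daily weather tibble, or `NULL` to skip heat/flood
#'   triggers.
#' @param drought Weekly drought tibble, or `NULL` to skip the drought
#'   trigger.
#' @param params A [detection_params()] object.
#' @return A tibble of alerts: `county`, `hazard`, `date`, `run_start`
#'   (heat only: the first day of the triggering run), `condition`.
#' @export
evaluate_triggers <- function(weather = NULL, drought = NULL,
                              params = detection_params()) {
  alerts <- list()
  if (!is.null(weather) && nrow(weather) > 0) {
    runs <- heat_runs(weather, params)
    ev <- filter(runs, .data$length >= params$min_run)
    if (nrow(ev) > 0) {
      alerts$heat <- bind_rows(lapply(seq_len(nrow(ev)), function(i) {
        dates <- seq(ev$start[i] + params$min_run - 1, ev$end[i], by = "day")
        tibble(
          county = ev$county[i], hazard = "heat", date = dates,
          run_start = ev$start[i],
          condition = sprintf("tmax >= %g degF for %d consecutive days since %s",
                              params$heat_threshold,
                              as.integer(dates - ev$start[i] + 1),
                              format(ev$start[i]))
        )
      }))
    }
    validate_weather(weather)
    wet <- filter(weather, !is.na(.data$precip_in),
                  .data$precip_in > params$precip_threshold)
    if (nrow(wet) > 0) {
      alerts$flood <- tibble(
        county = wet$county, hazard = "flood", date = wet$date,
        run_start = as.Date(NA),
        condition = sprintf("precipitation %.2f in > %g in", wet$precip_in,
                            params$precip_threshold)
      )
    }
  }
  if (!is.null(drought) && nrow(drought) > 0) {
    validate_drought(drought)
    dq <- drought[drought_level(drought$category) >=
                    drought_level(params$drought_min_severity), , drop = FALSE]
    if (nrow(dq) > 0) {
      alerts$drought <- tibble(
        county = dq$county, hazard = "drought", date = dq$week_start,
        run_start = as.Date(NA),
        condition = paste0("county declared in ", dq$category, " drought")
      )
    }
  }
  out <- bind_rows(alerts)
  if (nrow(out) == 0) {
    return(tibble(county = character(), hazard = character(),
                  date = as.Date(character()), run_start = as.Date(character()),
                  condition = character()))
  }
  arrange(out, .data$hazard, .data$county, .data$date)
}

#' Tabulate alerts and matched records over a reporting period
#'
#' @param alerts Alert tibble from [evaluate_triggers()].
#' @param matched Matched-record list from [match_reportable()].
#' @param period Length-2 `Date` window restricting the tabulation.
#' @return A list with `alert_counts` (tibble `hazard`, `county`,
#'   `n_alerts`) and `record_counts` (tibble `hazard`, `county`,
#'   `record_type`, `n_records`), both deterministic and independent of
#'   input row order.
#' @export
surveillance_report <- function(alerts, matched, period) {
  period <- as_date_strict(period, "period")
  stopifnot(length(period) == 2)
  a <- filter(alerts, .data$date >= period[1], .data$date <= period[2])
  alert_counts <- if (nrow(a) > 0) {
    arrange(summarise(group_by(a, .data$hazard, .data$county),
                      n_alerts = n(), .groups = "drop"),
            .data$hazard, .data$county)
  } else {
    tibble(hazard = character(), county = character(), n_alerts = integer())
  }
  rec <- bind_rows(lapply(setdiff(names(matched), "rejected"), function(hz) {
    df <- matched[[hz]]
    if (nrow(df) == 0) return(NULL)
    df$hazard <- hz
    df
  }))
  record_counts <- if (!is.null(rec) && nrow(rec) > 0) {
    rec <- filter(rec, .data$date >= period[1], .data$date <= period[2])
    arrange(summarise(group_by(rec, .data$hazard, .data$county, .data$record_type),
                      n_records = n(), .groups = "drop"),
            .data$hazard, .data$county, .data$record_type)
  } else {
    tibble(hazard = character(), county = character(),
           record_type = character(), n_records = integer())
  }
  list(alert_counts = alert_counts, record_counts = record_counts)
}
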