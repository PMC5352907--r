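#' Run the full district indicator pipeline
#'
#' Executes the stages end to end — exposure detection (heat events,
#' district consolidation, heavy-precipitation days, drought spells),
#' vulnerability classification, hazard-matrix assembly, and surveillance
#' (triggers plus reportable-outcome matching) — from a single
#' configuration, writing every stage output plus a manifest to the output
#' directory. Rerunning with identical inputs reproduces identical
#' outputs.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   `weather_csv`, `drought_csv`, `observations_csv`, `records_csv`
#'   (input paths; any may be omitted to skip the stages needing it),
#'   `registry_yaml` and `codes_yaml` (optional; defaults shipped with the
#'   package), `params` (a list of [detection_params()] arguments), and
#'   `out_dir`.
#' @return Invisibly, a list with `status` (0 on success) and `manifest`
#'   (stage outputs, file paths and parameter values). The manifest is
#'   also written to `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_stage("config", paste("Missing config file:", config))
    config <- yaml::read_yaml(config)
  }
  out_dir <- config$out_dir %||% stop_stage("config", "out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- do.call(detection_params, config$params %||% list())

  need_file <- function(path, stage) {
    if (!is.null(path) && !file.exists(path)) {
      stop_stage(stage, paste("Missing input file:", path))
    }
    path
  }
  registry <- if (!is.null(config$registry_yaml)) {
    read_registry(need_file(config$registry_yaml, "classify"))
  } else {
    default_registry()
  }
  code_sets <- default_code_sets(
    if (!is.null(config$codes_yaml)) need_file(config$codes_yaml, "surveil") else NULL
  )

  manifest <- list(params = unclass(params), files = list(), counts = list())
  write_out <- function(df, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(df, path, na = "")
    manifest$files[[name]] <<- path
    path
  }

  weather <- NULL
  if (!is.null(config$weather_csv)) {
    weather <- read_weather_csv(need_file(config$weather_csv, "detect"))
    message(sprintf("[detect] weather rows: %d", nrow(weather)))
    events <- detect_heat_events(weather, params)
    runs <- heat_runs(weather, params)
    district <- consolidate_district_events(events, runs, params)
    precip <- count_heavy_precip_days(weather, params)
    write_out(
      select(events, all_of(c("county", "start", "end", "duration_days", "peak_tmax_f"))),
      "heat_events.csv"
    )
    district_flat <- tibble(
      start = district$start, end = district$end,
      counties_affected = vapply(district$counties_affected, paste,
                                 character(1), collapse = ";"),
      near_threshold = vapply(district$near_threshold, function(nt) {
        paste(nt$county, collapse = ";")
      }, character(1))
    )
    write_out(district_flat, "district_events.csv")
    write_out(precip, "heavy_precip_days.csv")
    manifest$counts$heat_events <- nrow(events)
    manifest$counts$district_events <- nrow(district)
    message(sprintf("[detect] heat events: %d, district events: %d",
                    nrow(events), nrow(district)))
  }

  drought <- NULL
  if (!is.null(config$drought_csv)) {
    drought <- read_drought_csv(need_file(config$drought_csv, "detect"))
    spells <- extract_drought_spells(drought, params)
    write_out(spells, "drought_spells.csv")
    manifest$counts$drought_spells <- nrow(spells)
    message(sprintf("[detect] drought spells: %d", nrow(spells)))
  }

  if (!is.null(config$observations_csv)) {
    obs <- read_observations_csv(need_file(config$observations_csv, "classify"))
    tiers <- classify_table(obs, registry)
    write_out(tiers, "tiers.csv")
    mx <- build_matrix(tiers, registry)
    write_out(mx$entries, "hazard_matrix.csv")
    sm <- matrix_summary(mx)
    write_out(sm$per_county, "county_high_counts.csv")
    write_out(sm$per_indicator_hazard, "indicator_county_counts.csv")
    manifest$counts$observations <- nrow(obs)
    manifest$counts$min_high <- sm$min_high
    manifest$counts$max_high <- sm$max_high
    message(sprintf("[classify] observations: %d -> tiers: %d", nrow(obs), nrow(tiers)))
  }

  if (!is.null(weather) || !is.null(drought)) {
    alerts <- evaluate_triggers(weather, drought, params)
    write_out(alerts, "alerts.csv")
    manifest$counts$alerts <- nrow(alerts)
    message(sprintf("[surveil] alerts: %d", nrow(alerts)))
  }
  if (!is.null(config$records_csv)) {
    records <- read_records_csv(need_file(config$records_csv, "surveil"))
    matched <- match_reportable(records, code_sets)
    for (hz in setdiff(names(matched), "rejected")) {
      write_out(matched[[hz]], paste0("matched_", hz, ".csv"))
      manifest$counts[[paste0("matched_", hz)]] <- nrow(matched[[hz]])
    }
    write_out(matched$rejected, "rejected_records.csv")
    message(sprintf("[surveil] records: %d, rejected: %d",
                    nrow(records), nrow(matched$rejected)))
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(params = manifest$params, files = manifest$files,
         counts = manifest$counts),
    manifest_path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  manifest$files[["manifest.json"]] <- manifest_path
  invisible(list(status = 0L, manifest = manifest))
}

#' Render a district summary report from a pipeline manifest
#'
#' Produces a markdown summary with a section per hazard: detected events,
#' classification tiers, per-county high-vulnerability counts and alerts.
#' Every number is read back from the stage output files (single source of
#' truth), never recomputed.
#'
#' @param manifest A manifest list from [run_pipeline()], or the path to a
#'   written `manifest.json`.
#' @return A character vector of markdown lines, invisibly; also returned
#'   visibly via `cat` when `quiet = FALSE`.
#' @param quiet Suppress printing.
#' @export
render_report <- function(manifest, quiet = TRUE) {
  if (is.character(manifest) && length(manifest) == 1) {
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  }
  files <- manifest$files
  get_csv <- function(name) {
    path <- files[[name]]
    if (is.null(path) || !file.exists(path)) return(NULL)
    readr::read_csv(path, show_col_types = FALSE)
  }
  missing_arts <- character()
  lines <- c("# District climate-and-health summary", "")

  ev <- get_csv("heat_events.csv")
  lines <- c(lines, "## Extreme heat", "")
  if (!is.null(ev)) {
    lines <- c(lines, sprintf("- County heat events detected: %d", nrow(ev)))
    if (nrow(ev) > 0) {
      lines <- c(lines, sprintf("- Longest event: %d days", max(ev$duration_days)))
    }
  } else missing_arts <- c(missing_arts, "heat_events.csv")
  al <- get_csv("alerts.csv")
  if (!is.null(al)) {
    for (hz in c("heat", "drought", "flood")) {
      lines <- c(lines, sprintf("- %s alerts: %d", hz, sum(al$hazard == hz)))
    }
  }

  lines <- c(lines, "", "## Drought", "")
  sp <- get_csv("drought_spells.csv")
  if (!is.null(sp)) {
    lines <- c(lines, sprintf("- Drought spells (D2+): %d", nrow(sp)))
  }

  lines <- c(lines, "", "## Flooding", "")
  hp <- get_csv("heavy_precip_days.csv")
  if (!is.null(hp)) {
    lines <- c(lines, sprintf("- Heavy precipitation days (all counties, all years): %d",
                              sum(hp$heavy_precip_days)))
  }

  cc <- get_csv("county_high_counts.csv")
  lines <- c(lines, "", "## Vulnerability", "")
  if (!is.null(cc)) {
    lines <- c(lines, sprintf("- High-vulnerability indicators per county: %d to %d",
                              if (nrow(cc) > 0) min(cc$n_high) else 0L,
                              if (nrow(cc) > 0) max(cc$n_high) else 0L))
    lines <- c(lines, vapply(seq_len(nrow(cc)), function(i) {
      sprintf("  - %s: %d", cc$county[i], cc$n_high[i])
    }, character(1)))
  }

  if (is.null(ev) && is.null(sp) && is.null(cc)) {
    abort(paste("Manifest lists no readable stage outputs; missing:",
                paste(missing_arts, collapse = ", ")))
  }
  if (!quiet) cat(lines, sep = "\n")
  invisible(lines)
}
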