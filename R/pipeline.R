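#' Read and write the package's CSV schemas
#'
#' All tables are exchanged as UTF-8 CSV with ISO-8601 dates, empty fields
#' as the missing token, and areas as string ids. `read_area_day()` /
#' `write_area_day()` handle long `(area_id, date, value)` series;
#' `read_surveys()` / `write_surveys()` handle household survey records.
#' Reading validates the schema and reports offending row numbers;
#' write-then-read round-trips are identity (up to floating-point text
#' representation).
#'
#' @param x Table to write.
#' @param path CSV file path.
#' @return Readers return a tibble; writers return `path` invisibly.
#' @name schemas
NULL

#' @rdname schemas
#' @export
write_area_day <- function(x, path) {
  check_area_day(x)
  readr::write_csv(x |> mutate(date = format(date, "%Y-%m-%d")), path, na = "")
  invisible(path)
}

#' @rdname schemas
#' @export
read_area_day <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s.", path)
  raw <- readr::read_csv(path,
    col_types = readr::cols(
      area_id = readr::col_character(),
      date = readr::col_character(),
      value = readr::col_double()
    ), na = ""
  )
  need <- c("area_id", "date", "value")
  if (!all(need %in% names(raw))) {
    stopf("%s: expected columns %s.", path, toString(need))
  }
  d <- as.Date(raw$date, format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(raw$date))
  if (length(bad) > 0) {
    stopf(
      "%s: malformed date(s) at row(s) %s.", path,
      toString(head(bad, 5))
    )
  }
  raw |> mutate(date = d)
}

survey_cols <- function() {
  c(
    "area_id", "interview_date", "stratum", "weight_pop", "weight_demo",
    paste0("fg_", fcs_food_groups), paste0("cs_", rcsi_strategies)
  )
}

#' @rdname schemas
#' @export
write_surveys <- function(x, path) {
  miss <- setdiff(survey_cols(), names(x))
  if (length(miss) > 0) stopf("surveys table is missing columns: %s.", toString(miss))
  readr::write_csv(
    x[survey_cols()] |>
      mutate(interview_date = format(.data$interview_date, "%Y-%m-%d")),
    path,
    na = ""
  )
  invisible(path)
}

#' @rdname schemas
#' @export
read_surveys <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s.", path)
  raw <- readr::read_csv(path, col_types = readr::cols(
    area_id = readr::col_character(),
    interview_date = readr::col_character(),
    stratum = readr::col_character(),
    .default = readr::col_double()
  ), na = "")
  miss <- setdiff(survey_cols(), names(raw))
  if (length(miss) > 0) stopf("%s: missing columns %s.", path, toString(miss))
  d <- as.Date(raw$interview_date, format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(raw$interview_date))
  if (length(bad) > 0) {
    stopf("%s: malformed date(s) at row(s) %s.", path, toString(head(bad, 5)))
  }
  freq_cols <- c(paste0("fg_", fcs_food_groups), paste0("cs_", rcsi_strategies))
  for (cl in freq_cols) {
    bad <- which(!is.na(raw[[cl]]) & (raw[[cl]] < 0 | raw[[cl]] > 7))
    if (length(bad) > 0) {
      stopf("%s: `%s` out of [0,7] at row(s) %s.", path, cl, toString(head(bad, 5)))
    }
  }
  raw |> mutate(interview_date = d)
}

#' Assemble the forecasting design from a simulated (or loaded) scenario
#'
#' The canonical path from microdata to the design matrix: compute the
#' FCS-based prevalence of insufficient food consumption and the rCSI-based
#' crisis-coping prevalence via weighted rolling windows, interpolate
#' interior gaps, derive the daily driver features, screen the weather
#' variables with pairwise correlation pruning (|r| threshold on native
#' dekadal resolution), and build the lagged design matrix.
#'
#' @param scenario A [simulate_scenario()] result, or a list with elements
#'   `surveys`, `drivers`, `config`.
#' @param lags Lag specification passed to [build_design()].
#' @param horizons Forecast horizons.
#' @param prune_threshold Correlation threshold for the weather category.
#' @param use_statics Include static area attributes?
#' @return A list of class `scenario_design`: `design`, `prevalence_fcs`,
#'   `prevalence_rcsi`, `weather_pruning`, `vif`.
#' @export
assemble_design <- function(scenario,
                            lags = list(
                              target = 0:30, rcsi = 0:30,
                              driver = c(0, 7, 14, 30)
                            ),
                            horizons = 1:30,
                            prune_threshold = 0.45,
                            use_statics = TRUE) {
  cfg <- scenario$config
  d <- cfg$rolling_window_d
  rng <- range(scenario$surveys$interview_date)
  prev_fcs <- rolling_prevalence(scenario$surveys,
    d = d, indicator = "fcs",
    fcs = cfg$fcs, rcsi = cfg$rcsi, dates = rng
  ) |> interpolate_gaps()
  prev_rcsi <- rolling_prevalence(scenario$surveys,
    d = d, indicator = "rcsi",
    fcs = cfg$fcs, rcsi = cfg$rcsi, dates = rng
  ) |> interpolate_gaps()

  feats <- prepare_driver_features(scenario$drivers, d = d)

  # weather screening on native dekadal resolution
  wtab <- scenario$drivers$rainfall$dekads |>
    select(area_id, date, rainfall = "value") |>
    left_join(
      rainfall_anomaly(scenario$drivers$rainfall$dekads,
        scenario$drivers$rainfall$baseline,
        span = "1-month", daily = FALSE
      ) |> rename(rain_anom_1m = "value"),
      by = c("area_id", "date")
    ) |>
    left_join(
      rainfall_anomaly(scenario$drivers$rainfall$dekads,
        scenario$drivers$rainfall$baseline,
        span = "3-month", daily = FALSE
      ) |> rename(rain_anom_3m = "value"),
      by = c("area_id", "date")
    ) |>
    left_join(
      scenario$drivers$ndvi$dekads |> select(area_id, date, ndvi = "value"),
      by = c("area_id", "date")
    ) |>
    left_join(
      ndvi_anomaly(scenario$drivers$ndvi$dekads, scenario$drivers$ndvi$baseline,
        daily = FALSE
      ) |> rename(ndvi_anom = "value"),
      by = c("area_id", "date")
    )
  weather_names <- c("rainfall", "rain_anom_1m", "rain_anom_3m", "ndvi", "ndvi_anom")
  pruning <- correlation_prune(wtab[weather_names], threshold = prune_threshold)
  driver_list <- c(
    feats[c("fatalities", "price")],
    feats[intersect(weather_names, pruning$kept)],
    feats["ramadan"],
    list(rcsi = prev_rcsi)
  )
  statics <- if (use_statics) scenario$drivers$statics else NULL
  design <- build_design(prev_fcs,
    drivers = driver_list, statics = statics,
    lags = lags, horizons = horizons
  )
  vif <- tryCatch(
    vif_screen(
      design$features |>
        select(dplyr::all_of(paste0(
          setdiff(names(driver_list), "rcsi"), "_lag0"
        )))
    ),
    error = function(e) NULL
  )
  structure(
    list(
      design = design, prevalence_fcs = prev_fcs, prevalence_rcsi = prev_rcsi,
      weather_pruning = pruning, vif = vif
    ),
    class = "scenario_design"
  )
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run: the synthetic scenario, the
#' permutation-entropy settings, the design lags, the split count and the
#' learner grid. Unknown fields are rejected so typos fail loudly.
#'
#' @param scenario A [scenario_config()].
#' @param pe_m,pe_samples,pe_windows Embedding dimension, number of random
#'   start points, and window lengths of the predictability profile.
#' @param lags Design lag specification (see [build_design()]).
#' @param horizons Forecast horizons.
#' @param k Number of monthly evaluation splits.
#' @param grid Hyper-parameter grid.
#' @param seed Global seed of the run.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = scenario_config(),
                            pe_m = 3, pe_samples = 1000, pe_windows = 10:100,
                            lags = list(
                              target = 0:30, rcsi = 0:30,
                              driver = c(0, 7, 14, 30)
                            ),
                            horizons = 1:30, k = 5,
                            grid = default_hyper_grid(), seed = 1) {
  stopifnot(inherits(scenario, "scenario_config"))
  check_number(pe_m, "pe_m", min = 2, max = 7, integerish = TRUE)
  check_number(k, "k", min = 1, integerish = TRUE)
  check_number(seed, "seed", integerish = TRUE)
  structure(
    list(
      scenario = scenario, pe_m = pe_m, pe_samples = pe_samples,
      pe_windows = pe_windows, lags = lags, horizons = horizons,
      k = k, grid = grid, seed = seed
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' The YAML may set any [pipeline_config()] or [scenario_config()] field
#' (scenario fields under a `scenario:` key); unknown keys are rejected.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s.", path)
  y <- yaml::read_yaml(path)
  sc_args <- y$scenario %||% list()
  known_sc <- names(formals(scenario_config))
  unknown <- setdiff(names(sc_args), known_sc)
  if (length(unknown) > 0) stopf("unknown scenario field(s): %s.", toString(unknown))
  if (!is.null(sc_args$start_date)) sc_args$start_date <- as.Date(sc_args$start_date)
  y$scenario <- NULL
  known <- setdiff(names(formals(pipeline_config)), "scenario")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0) stopf("unknown config field(s): %s.", toString(unknown))
  do.call(pipeline_config, c(list(scenario = do.call(scenario_config, sc_args)), y))
}

#' Run the end-to-end pipeline into a run directory
#'
#' Executes simulate -> indicators -> predictability -> features/design ->
#' forecast -> evaluate, writing each stage's artifacts as CSV under
#' `out_dir` plus a `manifest.json` with seeds and file hashes. Stages
#' whose outputs already exist are skipped, so deleting a stage's files and
#' re-running resumes from there.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages?
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  path <- function(f) file.path(out_dir, f)
  stage <- function(name, outputs, fn) {
    if (all(file.exists(path(outputs)))) {
      say("[%s] outputs exist, skipping", name)
      return(invisible(NULL))
    }
    say("[%s] running", name)
    tryCatch(fn(), error = function(e) {
      stopf("stage `%s` failed: %s", name, conditionMessage(e))
    })
  }

  scen_file <- path("surveys.csv")
  stage("simulate", c("surveys.csv", "latent.csv"), function() {
    sc <- simulate_scenario(config$scenario)
    write_surveys(sc$surveys, path("surveys.csv"))
    write_area_day(sc$latent, path("latent.csv"))
    saveRDS(sc$drivers, path("drivers.rds"))
  })
  drivers <- readRDS(path("drivers.rds"))
  surveys <- read_surveys(scen_file)
  scenario <- list(config = config$scenario, surveys = surveys, drivers = drivers)

  stage("indicators", c("prevalence_fcs.csv", "prevalence_rcsi.csv"), function() {
    d <- config$scenario$rolling_window_d
    rng <- range(surveys$interview_date)
    fcs <- rolling_prevalence(surveys,
      d = d, indicator = "fcs",
      fcs = config$scenario$fcs, rcsi = config$scenario$rcsi, dates = rng
    ) |> interpolate_gaps()
    rcsi <- rolling_prevalence(surveys,
      d = d, indicator = "rcsi",
      fcs = config$scenario$fcs, rcsi = config$scenario$rcsi, dates = rng
    ) |> interpolate_gaps()
    write_area_day(fcs, path("prevalence_fcs.csv"))
    write_area_day(rcsi, path("prevalence_rcsi.csv"))
  })

  stage("predictability", "chi_profile.csv", function() {
    prev <- read_area_day(path("prevalence_fcs.csv")) |> filter(!is.na(value))
    curve <- predictability_profile(prev,
      window_lengths = config$pe_windows,
      n_samples = config$pe_samples, m = config$pe_m,
      seed = derive_seed(config$seed, "pe")
    )
    readr::write_csv(curve, path("chi_profile.csv"))
  })

  stage("forecast", "evaluation.csv", function() {
    asm <- assemble_design(scenario, lags = config$lags, horizons = config$horizons)
    splits <- make_splits(asm$design, k = config$k)
    ex <- run_forecast_experiment(asm$design, splits,
      horizons = config$horizons,
      grid = config$grid, seed = derive_seed(config$seed, "forecast")
    )
    readr::write_csv(ex$evaluations, path("evaluation.csv"))
    readr::write_csv(ex$predictions |> mutate(
      ref_date = format(.data$ref_date, "%Y-%m-%d"),
      target_date = format(.data$target_date, "%Y-%m-%d")
    ), path("predictions.csv"))
  })

  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("foodcast")),
    seed = config$seed,
    scenario_seed = config$scenario$seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    hashes = as.list(tools::md5sum(file.path(out_dir, files)) |>
      setNames(files))
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  say("done: %s", out_dir)
  invisible(manifest)
}
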