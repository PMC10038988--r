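#' Score model and naive predictions per split and horizon
#'
#' Computes, for every grouping cell (by default split and horizon, pooling
#' all areas), the coefficient of determination `R2 = 1 - SSE/SST` (with
#' the test-set mean as reference) and the mean squared error, for both the
#' forecasting model and the naive persistence baseline. Cells with zero
#' test variance have an undefined `R2`, reported as `NA` with a warning.
#'
#' @param predictions Tibble with columns `actual`, `pred_model`,
#'   `pred_naive` plus the grouping columns (e.g. from joining
#'   [predict_paths()] and [naive_forecast()] output).
#' @param by Grouping columns.
#' @return A tibble with one row per group: `r2_model`, `r2_naive`,
#'   `mse_model`, `mse_naive`, `n_test`.
#' @export
score_split <- function(predictions, by = c("split_id", "horizon")) {
  need <- c("actual", "pred_model", "pred_naive")
  if (!all(need %in% names(predictions))) {
    stopf("`predictions` must have columns %s.", toString(need))
  }
  by <- intersect(by, names(predictions))
  out <- predictions |>
    filter(!is.na(.data$actual)) |>
    group_by(dplyr::across(dplyr::all_of(by))) |>
    summarise(
      n_test = dplyr::n(),
      sst = sum((.data$actual - mean(.data$actual))^2),
      mse_model = mean((.data$actual - .data$pred_model)^2),
      mse_naive = mean((.data$actual - .data$pred_naive)^2),
      r2_model = ifelse(sst > 0, 1 - sum((.data$actual - .data$pred_model)^2) / sst, NA_real_),
      r2_naive = ifelse(sst > 0, 1 - sum((.data$actual - .data$pred_naive)^2) / sst, NA_real_),
      .groups = "drop"
    ) |>
    select(dplyr::all_of(by), "r2_model", "r2_naive", "mse_model", "mse_naive", "n_test")
  if (anyNA(out$r2_model)) {
    rlang::warn("zero test variance in some cells; R2 undefined there (NA).")
  }
  out
}

#' Model-vs-naive metric differences
#'
#' Adds `delta_r2 = r2_model - r2_naive` and `delta_mse = mse_naive -
#' mse_model` to a [score_split()] table: positive values mean the
#' forecasting model outperforms the persistence baseline.
#'
#' @param evaluations A [score_split()] result.
#' @return The input with `delta_r2` and `delta_mse` columns appended.
#' @export
delta_metrics <- function(evaluations) {
  need <- c("r2_model", "r2_naive", "mse_model", "mse_naive")
  if (!all(need %in% names(evaluations))) {
    stopf("`evaluations` must come from score_split().")
  }
  evaluations |>
    mutate(
      delta_r2 = .data$r2_model - .data$r2_naive,
      delta_mse = .data$mse_naive - .data$mse_model
    )
}

#' Run the full forecasting experiment over a split plan
#'
#' For each monthly split: fits horizon models on all data whose target
#' predates the test month, then scores every admissible forecast — each
#' (origin, horizon) pair whose origin lies before the test month and whose
#' target date falls inside it, so a horizon-`h` model is tested on `h`
#' origins per area. Every origin's information set predates the test
#' window, keeping the evaluation leak-free. The naive persistence
#' forecast is computed from the same origins. This is the engine behind
#' the split-evaluation and learning-curve analyses.
#'
#' @param design A [build_design()] object.
#' @param splits A [make_splits()] plan (or a subset of its rows).
#' @param horizons Horizons to evaluate; horizons longer than a split's
#'   test month are skipped for that split.
#' @param naive_series Series used for the persistence baseline; defaults
#'   to the design's target series.
#' @inheritParams fit_horizon_models
#' @param keep_models Also return the fitted model sets? (memory-heavy).
#' @return A list of class `forecast_experiment`: `evaluations` (scored
#'   per split x horizon, with deltas), `predictions` (row-level), and
#'   optionally `models`.
#' @export
run_forecast_experiment <- function(design, splits, horizons = design$horizons,
                                    grid = default_hyper_grid(),
                                    feature_sets = NULL, seed = 1,
                                    nrounds_max = 300,
                                    early_stopping_rounds = 25,
                                    validation_frac = 0.2, refit = TRUE,
                                    naive_series = NULL,
                                    keep_models = FALSE) {
  if (is.null(naive_series)) naive_series <- design$target
  all_pred <- list()
  models <- list()
  for (i in seq_len(nrow(splits))) {
    sp <- splits[i, ]
    month_len <- as.integer(sp$test_end - sp$test_start) + 1L
    hs <- horizons[horizons <= month_len]
    if (length(hs) == 0) next
    fit <- fit_horizon_models(design, sp,
      horizons = hs, grid = grid,
      feature_sets = feature_sets,
      seed = derive_seed(seed, sprintf("split%d", sp$split_id)),
      nrounds_max = nrounds_max,
      early_stopping_rounds = early_stopping_rounds,
      validation_frac = validation_frac, refit = refit
    )
    origins <- seq(sp$test_start - max(hs), sp$test_start - 1, by = "day")
    mp <- predict_paths(fit, design, ref_dates = origins) |>
      filter(
        .data$target_date >= sp$test_start,
        .data$target_date <= sp$test_end
      )
    np <- purrr::map(origins, function(o) {
      naive_forecast(naive_series, o, horizons = hs)
    }) |> purrr::list_rbind()
    all_pred[[i]] <- mp |>
      rename(pred_model = "pred") |>
      left_join(
        np |> select(area_id, "ref_date", "horizon", pred_naive = "pred"),
        by = c("area_id", "ref_date", "horizon")
      ) |>
      mutate(split_id = sp$split_id)
    if (keep_models) models[[as.character(sp$split_id)]] <- fit
  }
  predictions <- purrr::list_rbind(all_pred)
  evaluations <- predictions |>
    score_split(by = c("split_id", "horizon")) |>
    delta_metrics()
  structure(
    list(
      evaluations = evaluations, predictions = predictions,
      models = if (keep_models) models else NULL,
      splits = splits
    ),
    class = "forecast_experiment"
  )
}

#' @export
print.forecast_experiment <- function(x, ...) {
  cat(sprintf(
    "<forecast_experiment> %d splits, horizons %s\n",
    length(unique(x$evaluations$split_id)),
    paste(range(x$evaluations$horizon), collapse = "..")
  ))
  s <- x$evaluations |>
    group_by(horizon) |>
    summarise(
      r2_model = mean(r2_model), r2_naive = mean(r2_naive),
      delta_mse = mean(.data$delta_mse), .groups = "drop"
    )
  print(as.data.frame(head(s, 8)), row.names = FALSE)
  invisible(x)
}

#' Restrict an area-day series (or survey table) to a sub-scenario
#'
#' Learning-curve variants subsample the data either in time (keeping the
#' most recent `n_days`, so the evaluation months stay aligned across
#' variants) or in space (keeping the first `n_areas` areas), or both.
#'
#' @param x A long tibble with `area_id` and a date column (`date` or
#'   `interview_date`).
#' @param n_days Keep only the last `n_days` days (`NULL`: all).
#' @param n_areas Keep only the first `n_areas` areas in sorted id order
#'   (`NULL`: all).
#' @return The filtered tibble.
#' @export
subset_scenario <- function(x, n_days = NULL, n_areas = NULL) {
  date_col <- if ("date" %in% names(x)) "date" else "interview_date"
  if (!is.null(n_areas)) {
    keep <- sort(unique(x$area_id))[seq_len(n_areas)]
    x <- x |> filter(area_id %in% keep)
  }
  if (!is.null(n_days)) {
    last <- max(x[[date_col]])
    x <- x |> filter(.data[[date_col]] > last - n_days)
  }
  x
}

#' Learning curve: forecast skill versus training-set size
#'
#' Re-runs the full train/test experiment on nested dataset variants
#' (shorter histories at fixed area count, fewer areas at fixed history
#' length, or both) and aggregates the model-vs-naive MSE difference at
#' weekly horizons. The number of training points of a variant is the
#' count of area-day target observations available before its earliest
#' test month.
#'
#' @param variants Named list; each element is a list with elements
#'   `design` (a [build_design()] object), `scenario` (a label: `"full"`,
#'   `"fixed-length"`, `"fixed-areas"`, ...) and optionally `eval_areas`
#'   (area ids to score on). Scoring every variant of a family on the same
#'   area subset makes their skill differences reflect training data
#'   alone, not test-set composition.
#' @param horizons Weekly horizons to report (days).
#' @param k Number of monthly splits per variant.
#' @inheritParams run_forecast_experiment
#' @return A tibble: `variant`, `scenario`, `n_training_points`,
#'   `horizon`, `horizon_week`, `delta_mse_mean`, `delta_mse_sd`,
#'   `n_splits`.
#' @export
learning_curve <- function(variants, horizons = c(7, 14, 21, 28), k = 3,
                           grid = default_hyper_grid(), seed = 1,
                           nrounds_max = 300, early_stopping_rounds = 25,
                           min_train_days = 120) {
  purrr::imap(variants, function(v, nm) {
    design <- v$design
    splits <- tryCatch(
      make_splits(design, k = k, min_train_days = min_train_days),
      error = function(e) {
        rlang::warn(sprintf("variant %s skipped: %s", nm, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(splits)) {
      return(NULL)
    }
    n_train <- design$target |>
      filter(date < min(splits$test_start), !is.na(value)) |>
      nrow()
    ex <- run_forecast_experiment(design, splits,
      horizons = horizons,
      grid = grid, seed = derive_seed(seed, nm),
      nrounds_max = nrounds_max,
      early_stopping_rounds = early_stopping_rounds
    )
    evals <- if (is.null(v$eval_areas)) {
      ex$evaluations
    } else {
      ex$predictions |>
        filter(area_id %in% v$eval_areas) |>
        score_split(by = c("split_id", "horizon")) |>
        delta_metrics()
    }
    evals |>
      group_by(horizon) |>
      summarise(
        delta_mse_mean = mean(.data$delta_mse),
        delta_mse_sd = sd(.data$delta_mse),
        n_splits = dplyr::n(), .groups = "drop"
      ) |>
      mutate(
        variant = nm,
        scenario = v$scenario %||% "full",
        n_training_points = n_train,
        horizon_week = as.integer(ceiling(horizon / 7))
      )
  }) |>
    purrr::list_rbind() |>
    select(
      "variant", "scenario", "n_training_points", "horizon",
      "horizon_week", "delta_mse_mean", "delta_mse_sd", "n_splits"
    )
}
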