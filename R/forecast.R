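#' Time-ordered monthly evaluation splits
#'
#' Builds `k` disjoint test windows, each one calendar month long, taken
#' from the tail of the target series (the last `k` complete months). For
#' every split, all information up to the day before the test month is the
#' training + validation region; no training row's target date falls inside
#' the test window.
#'
#' @param design A [build_design()] object (its target series defines the
#'   calendar).
#' @param k Number of monthly splits.
#' @param min_train_days Minimum days of history required before the
#'   earliest test month.
#' @return A tibble of class `split_plan`: `split_id`, `test_start`,
#'   `test_end`.
#' @export
make_splits <- function(design, k = 5, min_train_days = 120) {
  stopifnot(inherits(design, "feature_design"))
  check_number(k, "k", min = 1, integerish = TRUE)
  last <- max(design$target$date)
  first <- min(design$target$date)
  # last complete month covered by the series
  last_month <- as.Date(format(last, "%Y-%m-01"))
  if (month_end(last_month) > last) last_month <- prev_month(last_month)
  starts <- last_month
  for (i in seq_len(k - 1)) starts <- c(prev_month(min(starts)), starts)
  need <- min_train_days + max(design$horizons)
  if (min(starts) - need < first) {
    stopf(
      "series starting %s is too short for %d monthly splits: the earliest test month (%s) needs %d prior days.",
      format(first), k, format(min(starts)), need
    )
  }
  out <- tibble(
    split_id = seq_len(k),
    test_start = starts,
    test_end = as.Date(vapply(starts, function(s) as.character(month_end(s)), character(1)))
  )
  class(out) <- c("split_plan", class(out))
  out
}

month_end <- function(month_start) {
  seq(month_start, by = "month", length.out = 2)[2] - 1
}
prev_month <- function(month_start) {
  seq(month_start, by = "-1 month", length.out = 2)[2]
}

#' Default hyper-parameter grid for the boosted-tree learner
#'
#' Tree depth, learning rate and row subsampling are searched on the
#' validation set; the number of boosting rounds is chosen by early
#' stopping rather than being a grid axis.
#'
#' @return A tibble of candidate configurations.
#' @export
default_hyper_grid <- function() {
  tidyr::expand_grid(
    max_depth = c(3L, 5L, 7L),
    eta = c(0.05, 0.1),
    subsample = c(0.8, 1.0)
  )
}

#' Fit one boosted-tree model per forecast horizon
#'
#' For each horizon `h`, training rows are the design rows whose target date
#' precedes the split's test month. The first 80% of those rows (in time
#' order) train each candidate configuration; the remaining 20% validate
#' it (early stopping on validation RMSE picks the number of rounds). The
#' candidate with the lowest validation RMSE wins — optionally among
#' feature-lag presets as well — and is refit on the full training region
#' before testing. Fully deterministic given `seed`.
#'
#' @param design A [build_design()] object.
#' @param split One row of a [make_splits()] plan.
#' @param horizons Horizons to fit (default: all of the design's).
#' @param grid Hyper-parameter tibble (see [default_hyper_grid()]); may
#'   carry a `feature_set` column naming entries of `feature_sets`.
#' @param feature_sets Named list of feature-column subsets (lag presets);
#'   `NULL` uses all features for every candidate.
#' @param seed Integer seed controlling learner randomness.
#' @param nrounds_max Maximum boosting rounds.
#' @param early_stopping_rounds Patience of validation early stopping.
#' @param validation_frac Tail fraction of the training region held out for
#'   validation.
#' @param refit Refit the winning configuration on the full training region
#'   (train + validation) before testing? If `FALSE` the validated model is
#'   used as-is.
#' @return An object of class `horizon_model_set`.
#' @export
fit_horizon_models <- function(design, split, horizons = design$horizons,
                               grid = default_hyper_grid(),
                               feature_sets = NULL,
                               seed = 1, nrounds_max = 300,
                               early_stopping_rounds = 25,
                               validation_frac = 0.2, refit = TRUE) {
  stopifnot(inherits(design, "feature_design"))
  if (nrow(grid) == 0) stopf("`grid` must contain at least one candidate.")
  split <- as.list(split[1, ])
  feat_cols <- design_feature_cols(design)
  models <- list()
  for (h in sort(unique(as.integer(horizons)))) {
    rows <- design_rows(design, h) |>
      filter(.data$target_date < split$test_start) |>
      arrange(.data$ref_date, area_id)
    if (nrow(rows) < 30) {
      stopf("horizon %d has only %d training rows before %s.", h, nrow(rows), format(split$test_start))
    }
    n <- nrow(rows)
    n_train <- floor((1 - validation_frac) * n)
    x <- as.matrix(rows[feat_cols])
    y <- rows$target
    dtrain <- xgboost::xgb.DMatrix(x[seq_len(n_train), , drop = FALSE],
      label = y[seq_len(n_train)]
    )
    dval <- xgboost::xgb.DMatrix(x[(n_train + 1):n, , drop = FALSE],
      label = y[(n_train + 1):n]
    )
    best <- NULL
    for (ci in seq_len(nrow(grid))) {
      cand <- as.list(grid[ci, ])
      use_cols <- feat_cols
      if (!is.null(cand$feature_set)) {
        if (is.null(feature_sets) || is.null(feature_sets[[cand$feature_set]])) {
          stopf("unknown feature set `%s`.", cand$feature_set)
        }
        use_cols <- intersect(feat_cols, feature_sets[[cand$feature_set]])
      }
      params <- list(
        objective = "reg:squarederror",
        max_depth = cand$max_depth %||% 5L,
        eta = cand$eta %||% 0.1,
        subsample = cand$subsample %||% 1.0,
        nthread = 1L
      )
      dtr <- if (identical(use_cols, feat_cols)) {
        dtrain
      } else {
        xgboost::xgb.DMatrix(x[seq_len(n_train), use_cols, drop = FALSE],
          label = y[seq_len(n_train)]
        )
      }
      dva <- if (identical(use_cols, feat_cols)) {
        dval
      } else {
        xgboost::xgb.DMatrix(x[(n_train + 1):n, use_cols, drop = FALSE],
          label = y[(n_train + 1):n]
        )
      }
      set.seed(derive_seed(seed, sprintf("fit_h%d_c%d", h, ci)))
      booster <- xgboost::xgb.train(
        params = params, data = dtr, nrounds = nrounds_max,
        evals = list(val = dva),
        early_stopping_rounds = early_stopping_rounds, verbose = 0
      )
      val_rmse <- as.numeric(xgboost::xgb.attr(booster, "best_score"))
      best_iter <- as.integer(xgboost::xgb.attr(booster, "best_iteration"))
      if (is.null(best) || val_rmse < best$val_rmse - 1e-15) {
        best <- list(
          booster = booster, params = params, candidate = ci,
          val_rmse = val_rmse, nrounds = max(best_iter, 1L),
          feature_cols = use_cols
        )
      }
    }
    if (refit) {
      dfull <- xgboost::xgb.DMatrix(x[, best$feature_cols, drop = FALSE], label = y)
      set.seed(derive_seed(seed, sprintf("refit_h%d", h)))
      best$booster <- xgboost::xgb.train(
        params = best$params, data = dfull, nrounds = best$nrounds, verbose = 0
      )
    }
    models[[as.character(h)]] <- best
  }
  structure(
    list(
      models = models, split = split, seed = seed,
      feature_cols = feat_cols, refit = refit
    ),
    class = "horizon_model_set"
  )
}

#' @export
print.horizon_model_set <- function(x, ...) {
  cat(sprintf(
    "<horizon_model_set> %d horizon models; test month starting %s; seed %d\n",
    length(x$models), format(x$split$test_start), x$seed
  ))
  invisible(x)
}

#' Naive persistence forecast
#'
#' The naive baseline predicts, for every horizon, the last available value
#' of the series at or before the reference date — the final measurement in
#' the training and validation region. It is horizon-independent by
#' definition.
#'
#' @param series Long area-day tibble of the target prevalence.
#' @param reference_date Date of the forecast origin.
#' @param horizons Horizons in days.
#' @return A tibble `(area_id, ref_date, horizon, target_date, pred)`.
#' @export
naive_forecast <- function(series, reference_date, horizons = 1:30) {
  check_area_day(series)
  reference_date <- as_date_checked(reference_date, "reference_date")
  last_vals <- series |>
    filter(date <= reference_date, !is.na(value)) |>
    group_by(area_id) |>
    slice_max(date, n = 1, with_ties = FALSE) |>
    ungroup()
  if (nrow(last_vals) == 0) {
    stopf("no observed value at or before %s.", format(reference_date))
  }
  tidyr::expand_grid(
    last_vals |> select(area_id, pred = "value"),
    horizon = as.integer(horizons)
  ) |>
    mutate(
      ref_date = reference_date,
      target_date = reference_date + .data$horizon
    ) |>
    select(area_id, "ref_date", "horizon", "target_date", "pred")
}

#' Predict forecast paths from a fitted horizon model set
#'
#' Applies each horizon model to the design rows at the given reference
#' date(s); predictions are clipped to `[0, 1]` since the target is a
#' prevalence. Rows with missing features are predicted through the
#' learner's default missing-value routing — no row is dropped. When the
#' design holds the realised target (synthetic truth or later
#' measurements), it is returned alongside as `actual`.
#'
#' @param model_set A [fit_horizon_models()] result.
#' @param design The [build_design()] object the models were fitted on.
#' @param ref_dates Forecast origin date(s); default: the day before the
#'   model set's test month.
#' @return A tibble `(area_id, ref_date, horizon, target_date, pred,
#'   actual)`.
#' @export
predict_paths <- function(model_set, design, ref_dates = NULL) {
  stopifnot(inherits(model_set, "horizon_model_set"), inherits(design, "feature_design"))
  if (is.null(ref_dates)) ref_dates <- model_set$split$test_start - 1
  ref_dates <- as_date_checked(ref_dates, "ref_dates")
  purrr::map(names(model_set$models), function(hn) {
    h <- as.integer(hn)
    best <- model_set$models[[hn]]
    rows <- design_rows(design, h, drop_na_target = FALSE) |>
      filter(.data$ref_date %in% ref_dates)
    if (nrow(rows) == 0) {
      return(NULL)
    }
    missing_cols <- setdiff(best$feature_cols, names(rows))
    if (length(missing_cols) > 0) {
      stopf("design lacks feature columns: %s.", toString(missing_cols))
    }
    x <- as.matrix(rows[best$feature_cols])
    p <- predict(best$booster, xgboost::xgb.DMatrix(x))
    rows |>
      transmute(
        area_id,
        ref_date = .data$ref_date, horizon = .data$horizon,
        target_date = .data$target_date,
        pred = pmin(1, pmax(0, as.numeric(p))),
        actual = .data$target
      )
  }) |> purrr::list_rbind()
}
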