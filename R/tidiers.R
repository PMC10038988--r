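#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted horizon model set
#'
#' One row per horizon with the selected hyper-parameters, boosting rounds
#' and validation RMSE.
#'
#' @param x A [fit_horizon_models()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.horizon_model_set <- function(x, ...) {
  purrr::imap(x$models, function(m, hn) {
    tibble(
      horizon = as.integer(hn),
      candidate = m$candidate,
      max_depth = m$params$max_depth,
      eta = m$params$eta,
      subsample = m$params$subsample,
      nrounds = m$nrounds,
      val_rmse = m$val_rmse,
      n_features = length(m$feature_cols)
    )
  }) |>
    purrr::list_rbind() |>
    arrange(horizon)
}

#' @rdname tidy.horizon_model_set
#' @export
glance.horizon_model_set <- function(x, ...) {
  td <- tidy(x)
  tibble(
    n_horizons = nrow(td),
    test_start = x$split$test_start,
    mean_val_rmse = mean(td$val_rmse),
    refit = x$refit,
    seed = x$seed
  )
}

#' Tidy a forecast experiment
#'
#' Returns the per-split, per-horizon evaluation table (R2 and MSE for the
#' model and the naive baseline plus their differences); `glance()`
#' summarises it across splits.
#'
#' @param x A [run_forecast_experiment()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.forecast_experiment <- function(x, ...) x$evaluations

#' @rdname tidy.forecast_experiment
#' @export
glance.forecast_experiment <- function(x, ...) {
  x$evaluations |>
    summarise(
      n_splits = dplyr::n_distinct(.data$split_id),
      n_horizons = dplyr::n_distinct(horizon),
      mean_r2_model = mean(.data$r2_model, na.rm = TRUE),
      mean_r2_naive = mean(.data$r2_naive, na.rm = TRUE),
      mean_delta_mse = mean(.data$delta_mse),
      share_model_wins = mean(.data$delta_mse > 0)
    )
}

#' Tidy an ordinal pattern distribution
#'
#' Pattern frequencies with probabilities; `glance()` returns the entropy
#' summary.
#'
#' @param x An [ordinal_patterns()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ordinal_distribution <- function(x, ...) {
  tibble(
    pattern = x$pattern, count = x$count,
    p = x$count / attr(x, "n_windows")
  )
}

#' @rdname tidy.ordinal_distribution
#' @export
glance.ordinal_distribution <- function(x, ...) {
  h <- permutation_entropy(x, normalized = TRUE)
  tibble(
    m = attr(x, "m"), tau = attr(x, "tau"),
    n_windows = attr(x, "n_windows"),
    n_patterns = nrow(x),
    entropy = permutation_entropy(x, normalized = FALSE),
    entropy_normalized = h,
    chi = predictability(h)
  )
}
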