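#' Plot a predictability profile
#'
#' Mean predictability `chi = 1 - H` versus window length, with the
#' interquartile band across areas and window placements shaded.
#'
#' @param object A [predictability_profile()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.predictability_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$window_length)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_chi), colour = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "window length (days)",
      y = expression(paste("predictability  ", chi == 1 - H)),
      title = "Intrinsic predictability vs. time-series length"
    ) +
    ggplot2::theme_minimal()
}

#' Plot model-vs-naive skill across horizons
#'
#' Per-horizon distributions (across splits) of the model and naive R2,
#' and of the MSE difference `mse_naive - mse_model` (positive = the model
#' outperforms persistence).
#'
#' @param object A [run_forecast_experiment()] result.
#' @param metric `"r2"` or `"delta_mse"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.forecast_experiment <- function(object, metric = c("r2", "delta_mse"), ...) {
  metric <- match.arg(metric)
  ev <- object$evaluations
  if (metric == "r2") {
    long <- ev |>
      tidyr::pivot_longer(c("r2_model", "r2_naive"),
        names_to = "model", values_to = "r2"
      ) |>
      mutate(model = ifelse(.data$model == "r2_model", "forecast model", "naive"))
    ggplot2::ggplot(long, ggplot2::aes(
      factor(.data$horizon), .data$r2,
      colour = .data$model
    )) +
      ggplot2::geom_boxplot(outlier.size = 0.6) +
      ggplot2::labs(
        x = "forecast horizon (days)", y = expression(R^2),
        colour = NULL, title = "Forecast skill by horizon"
      ) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(ev, ggplot2::aes(factor(.data$horizon), .data$delta_mse)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
      ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.4, outlier.size = 0.6) +
      ggplot2::labs(
        x = "forecast horizon (days)",
        y = expression(MSE[naive] - MSE[model]),
        title = "Model advantage over persistence"
      ) +
      ggplot2::theme_minimal()
  }
}

#' Plot a learning curve
#'
#' Mean model-vs-naive MSE difference at weekly horizons against the number
#' of training points, one panel per scenario variant; the region above
#' zero is where the forecasting model beats persistence.
#'
#' @param curve A [learning_curve()] result.
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(
    .data$n_training_points, .data$delta_mse_mean,
    colour = factor(.data$horizon_week), group = factor(.data$horizon_week)
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$delta_mse_mean - .data$delta_mse_sd,
      ymax = .data$delta_mse_mean + .data$delta_mse_sd
    ), position = ggplot2::position_dodge(width = 0.05)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(
      x = "training points (area-days)",
      y = expression(MSE[naive] - MSE[model]),
      colour = "horizon (weeks)",
      title = "Forecast skill vs. training-set size"
    ) +
    ggplot2::theme_minimal()
}

#' Predicted-versus-actual scatter of forecast paths
#'
#' @param predictions The `predictions` tibble of a
#'   [run_forecast_experiment()].
#' @return A ggplot object.
#' @export
plot_pred_vs_actual <- function(predictions) {
  ggplot2::ggplot(
    predictions |> filter(!is.na(.data$actual)),
    ggplot2::aes(.data$actual, .data$pred_model, colour = .data$horizon)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey40") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "actual prevalence", y = "predicted prevalence",
      colour = "horizon (days)"
    ) +
    ggplot2::theme_minimal()
}
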