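#' Assemble daily driver feature series from a driver bundle
#'
#' Turns the raw driver bundle (events, dekads, monthly prices, calendar)
#' into daily area-day series ready for the lagged design matrix: the
#' trailing `d`-day fatality sum, normalized area prices, daily-expanded
#' rainfall and NDVI with their percent-of-average anomalies, and the
#' Ramadan window counter. Weather variables can then be screened with
#' [correlation_prune()] before entering the design.
#'
#' @param drivers A [generate_drivers()] bundle (or any list with the same
#'   shape).
#' @param d Rolling window length in days.
#' @param train_end Optional cutoff date for the leakage-safe price
#'   normalization (see [monthly_price()]); `NULL` normalizes by each
#'   market's first price.
#' @return A named list of long tibbles: `fatalities`, `price`, `rainfall`,
#'   `rain_anom_1m`, `rain_anom_3m`, `ndvi`, `ndvi_anom` (area-day) and
#'   `ramadan` (`date`, `value`; common to all areas).
#' @export
prepare_driver_features <- function(drivers, d = 28, train_end = NULL) {
  all_dates <- seq(min(drivers$fatalities$date), max(drivers$fatalities$date), by = "day")
  list(
    fatalities = aggregate_fatalities(drivers$fatalities, d = d),
    price = if (is.null(train_end)) {
      monthly_price(drivers$prices, normalize = "first")
    } else {
      monthly_price(drivers$prices, normalize = "mean", train_end = train_end)
    },
    rainfall = dekads_to_daily(drivers$rainfall$dekads |>
      select(area_id, date, value)),
    rain_anom_1m = rainfall_anomaly(drivers$rainfall$dekads,
      drivers$rainfall$baseline,
      span = "1-month"
    ),
    rain_anom_3m = rainfall_anomaly(drivers$rainfall$dekads,
      drivers$rainfall$baseline,
      span = "3-month"
    ),
    ndvi = dekads_to_daily(drivers$ndvi$dekads |>
      select(area_id, date, value)),
    ndvi_anom = ndvi_anomaly(drivers$ndvi$dekads, drivers$ndvi$baseline),
    ramadan = ramadan_counter(all_dates, drivers$ramadan_intervals, d = d)
  )
}

#' Build the lagged design matrix for multi-horizon forecasting
#'
#' One design underlies all 30 horizon models: for every `(area,
#' reference_date)` it collects lagged values of the target prevalence, of
#' the rCSI crisis prevalence, and of each driver series — all dated at or
#' before the reference date, never after — plus static area attributes.
#' Horizon-specific rows (with the target `h` days after the reference date
#' and the temporal identifiers day/month/year of that future date) are
#' materialised lazily by [design_rows()], which keeps memory proportional
#' to one horizon at a time.
#'
#' @param target Long area-day tibble of the (gap-interpolated) prevalence
#'   of insufficient food consumption.
#' @param drivers Named list of feature series: area-day tibbles
#'   `(area_id, date, value)`, or `(date, value)` tibbles shared by all
#'   areas (e.g. the Ramadan counter). Include the rCSI prevalence here
#'   under the name `rcsi` to give it target-style lags.
#' @param statics Optional tibble of per-area attributes (`area_id` plus
#'   numeric columns: population, total area, latitude, longitude,
#'   waterways size).
#' @param lags Named list of integer lag vectors (days): `target`, `rcsi`
#'   and `driver` (the default for every other driver); a lag vector named
#'   after a specific driver overrides the default.
#' @param horizons Forecast horizons in days.
#' @return An object of class `feature_design`.
#' @export
build_design <- function(target, drivers = list(), statics = NULL,
                         lags = list(
                           target = 0:30, rcsi = 0:30,
                           driver = c(0, 7, 14, 30)
                         ),
                         horizons = 1:30) {
  check_area_day(target, "target")
  horizons <- sort(unique(as.integer(horizons)))
  if (any(horizons < 1)) stopf("`horizons` must be >= 1.")
  areas <- sort(unique(target$area_id))
  rng <- range(target$date)
  days <- seq(rng[1], rng[2], by = "day")
  grid <- tidyr::expand_grid(area_id = areas, ref_date = days)

  join_series <- function(grid, series, nm) {
    if (!"area_id" %in% names(series)) {
      series <- tidyr::expand_grid(area_id = areas, series)
    }
    grid |>
      left_join(
        series |> select(area_id, ref_date = "date", !!nm := "value"),
        by = c("area_id", "ref_date")
      )
  }

  base <- join_series(grid, target, ".target")
  for (nm in names(drivers)) base <- join_series(base, drivers[[nm]], nm)

  base <- base |>
    group_by(area_id) |>
    arrange(.data$ref_date, .by_group = TRUE)
  lag_for <- function(nm) {
    if (nm %in% names(lags)) {
      lags[[nm]]
    } else if (nm == ".target") {
      lags$target
    } else {
      lags$driver %||% c(0, 7, 14, 30)
    }
  }
  lag_cols <- character()
  for (nm in c(".target", names(drivers))) {
    out_nm <- if (nm == ".target") "target" else nm
    for (L in sort(unique(as.integer(lag_for(nm))))) {
      if (L < 0) stopf("lags must be >= 0 (no future information).")
      col <- sprintf("%s_lag%d", out_nm, L)
      lag_cols <- c(lag_cols, col)
      base <- base |> mutate(!!col := dplyr::lag(.data[[nm]], L))
    }
  }
  feat <- base |>
    ungroup() |>
    select(area_id, "ref_date", dplyr::all_of(lag_cols))

  if (!is.null(statics)) {
    if (!"area_id" %in% names(statics)) stopf("`statics` needs an area_id column.")
    feat <- feat |> left_join(statics, by = "area_id")
  }
  structure(
    list(
      features = feat,
      target = target |> arrange(area_id, date),
      horizons = horizons,
      feature_names = setdiff(names(feat), c("area_id", "ref_date")),
      lags = lags
    ),
    class = "feature_design"
  )
}

#' @export
print.feature_design <- function(x, ...) {
  cat(sprintf(
    "<feature_design> %d areas, %d reference dates, %d features, horizons %d..%d\n",
    length(unique(x$features$area_id)),
    length(unique(x$features$ref_date)),
    length(x$feature_names), min(x$horizons), max(x$horizons)
  ))
  invisible(x)
}

#' Materialise the design rows of one forecast horizon
#'
#' Joins the lagged feature block with the target value `h` days after each
#' reference date and appends the temporal identifiers (day, month, year)
#' of the forecast date. Rows with a missing target are dropped (nothing to
#' learn from); rows with missing features are kept — the boosted-tree
#' learner routes missing values natively.
#'
#' @param design A [build_design()] object.
#' @param h Horizon in days.
#' @param drop_na_target Drop rows whose target is missing?
#' @return A tibble: `area_id`, `ref_date`, `horizon`, `target_date`,
#'   `target`, then feature columns (including `cal_day`, `cal_month`,
#'   `cal_year` of the forecast date).
#' @export
design_rows <- function(design, h, drop_na_target = TRUE) {
  stopifnot(inherits(design, "feature_design"))
  check_number(h, "h", min = 1, integerish = TRUE)
  tgt <- design$target |>
    mutate(ref_date = date - h) |>
    select(area_id, "ref_date", target = "value")
  rows <- design$features |>
    inner_join(tgt, by = c("area_id", "ref_date")) |>
    mutate(
      horizon = as.integer(h),
      target_date = .data$ref_date + h,
      cal_day = as.integer(format(.data$target_date, "%d")),
      cal_month = as.integer(format(.data$target_date, "%m")),
      cal_year = as.integer(format(.data$target_date, "%Y"))
    )
  if (drop_na_target) rows <- rows |> filter(!is.na(.data$target))
  rows |>
    select(
      area_id, "ref_date", "horizon", "target_date", "target",
      dplyr::all_of(design$feature_names), "cal_day", "cal_month", "cal_year"
    ) |>
    arrange(.data$ref_date, area_id)
}

design_feature_cols <- function(design) {
  c(design$feature_names, "cal_day", "cal_month", "cal_year")
}
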