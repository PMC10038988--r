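#' Trailing-window sum of conflict fatalities
#'
#' Aligns the fatality information with the prevalence target: the value at
#' `(area, t)` is the sum of all reported fatalities in that area during the
#' previous `d` days, i.e. event dates in the half-open window `(t - d, t]`.
#' Days with no events contribute zero.
#'
#' @param events Tibble with `area_id`, `date`, and a fatality count column
#'   (`value` or `fatalities`); several events per day are allowed.
#' @param d Window length in days.
#' @param dates Optional length-2 date range for the output grid; defaults
#'   to the range of event dates.
#' @return A long area-day tibble `(area_id, date, value)` of window sums.
#' @examples
#' ev <- tibble::tibble(
#'   area_id = "A",
#'   date = as.Date("2021-01-05"), value = 5
#' )
#' aggregate_fatalities(ev, d = 3, dates = as.Date(c("2021-01-04", "2021-01-09")))
#' @export
aggregate_fatalities <- function(events, d = 28, dates = NULL) {
  check_number(d, "d", min = 1, integerish = TRUE)
  if ("fatalities" %in% names(events) && !"value" %in% names(events)) {
    events <- rename(events, value = "fatalities")
  }
  check_area_day(events, "events")
  if (any(events$value < 0)) stopf("fatality counts must be >= 0.")
  rng <- if (is.null(dates)) range(events$date) else as_date_checked(dates, "dates")
  grid <- tidyr::expand_grid(
    area_id = sort(unique(events$area_id)),
    date = seq(rng[1], rng[2], by = "day")
  )
  daily <- events |>
    filter(date >= rng[1], date <= rng[2]) |>
    group_by(area_id, date) |>
    summarise(value = sum(value), .groups = "drop")
  grid |>
    left_join(daily, by = c("area_id", "date")) |>
    mutate(value = tidyr::replace_na(value, 0)) |>
    group_by(area_id) |>
    arrange(date, .by_group = TRUE) |>
    mutate(value = roll_sum(value, d)) |>
    ungroup()
}

#' Area-level monthly price series from market prices
#'
#' Normalizes each market's series (unit-free local-currency prices) and
#' averages the normalized series across all markets of an area, then
#' forward-fills to daily resolution (each day carries its month's value).
#'
#' @param prices Tibble with `area_id`, `market_id`, `month` (Date, first of
#'   month), `price` (> 0).
#' @param normalize `"mean"` divides each market by its own mean price up to
#'   `train_end` (leakage-safe when `train_end` is the training cutoff);
#'   `"first"` divides by the market's first recorded price;
#'   `"none"` leaves prices untouched.
#' @param train_end Optional cutoff date for the `"mean"` normalization.
#' @param daily Expand to daily resolution? If `FALSE`, returns monthly rows.
#' @return A long area-day (or area-month) tibble `(area_id, date, value)`.
#' @export
monthly_price <- function(prices, normalize = c("mean", "first", "none"),
                          train_end = NULL, daily = TRUE) {
  normalize <- match.arg(normalize)
  need <- c("area_id", "market_id", "month", "price")
  if (!all(need %in% names(prices))) {
    stopf("`prices` must have columns %s.", toString(need))
  }
  if (any(prices$price <= 0, na.rm = TRUE)) stopf("prices must be > 0.")
  norm <- prices |>
    group_by(area_id, .data$market_id) |>
    arrange(.data$month, .by_group = TRUE) |>
    mutate(value = switch(normalize,
      none = .data$price,
      first = .data$price / .data$price[1],
      mean = {
        ref <- if (is.null(train_end)) {
          .data$price
        } else {
          .data$price[.data$month <= as.Date(train_end)]
        }
        if (length(ref) == 0) stopf("no prices at or before `train_end`.")
        .data$price / mean(ref)
      }
    )) |>
    ungroup() |>
    group_by(area_id, month = .data$month) |>
    summarise(value = mean(value), .groups = "drop")
  if (!daily) {
    return(norm |> rename(date = "month"))
  }
  norm |>
    group_by(area_id) |>
    reframe({
      last_day <- seq(max(month), by = "month", length.out = 2)[2] - 1
      days <- seq(min(month), last_day, by = "day")
      tibble(
        date = days,
        value = value[match(as.Date(format(days, "%Y-%m-01")), month)]
      )
    }) |>
    ungroup()
}

#' Rainfall anomaly relative to the historical seasonal baseline
#'
#' Percent-of-average convention: the anomaly over a trailing span is
#' `100 * (observed rainfall sum) / (baseline sum over the same dekads of
#' the year)`, so 100 means a normal season, 200 twice the usual rain.
#' Dekadal values are repeated to daily resolution (each day carries the
#' value of the dekad it falls in).
#'
#' @param dekads Tibble `(area_id, date, value)` of dekadal observations,
#'   `date` being the dekad start; a `dekad` column (1..36) is recomputed if
#'   absent.
#' @param baseline Tibble `(area_id, dekad, mean)` of historical dekad means.
#' @param span Trailing window: `"1-month"` (3 dekads), `"3-month"`
#'   (9 dekads) or `"dekad"` (the current dekad only, as used for NDVI).
#' @param daily Expand to daily resolution?
#' @return A long tibble `(area_id, date, value)` of anomalies in percent;
#'   `NA` where the baseline sum is zero.
#' @export
rainfall_anomaly <- function(dekads, baseline,
                             span = c("1-month", "3-month", "dekad"),
                             daily = TRUE) {
  span <- match.arg(span)
  check_area_day(dekads, "dekads")
  if (!all(c("area_id", "dekad", "mean") %in% names(baseline))) {
    stopf("`baseline` must have columns area_id, dekad, mean.")
  }
  n_dek <- switch(span, "1-month" = 3L, "3-month" = 9L, dekad = 1L)
  anom <- dekads |>
    mutate(dekad = dekad_of_year(date)) |>
    left_join(baseline, by = c("area_id", "dekad")) |>
    group_by(area_id) |>
    arrange(date, .by_group = TRUE) |>
    mutate(
      obs = roll_sum(value, n_dek),
      ref = roll_sum(mean, n_dek),
      value = ifelse(ref > 0, 100 * obs / ref, NA_real_)
    ) |>
    ungroup() |>
    select(area_id, date, value)
  if (any(is.na(anom$value))) {
    rlang::warn("zero baseline in some dekads; anomaly set to NA there.")
  }
  if (!daily) {
    return(anom)
  }
  dekads_to_daily(anom)
}

#' NDVI anomaly relative to the historical dekad baseline
#'
#' Same percent-of-average convention as [rainfall_anomaly()] but over a
#' single dekad: vegetation already integrates the effect of previous
#' rainfall, so no multi-dekad window is used.
#'
#' @inheritParams rainfall_anomaly
#' @return A long tibble `(area_id, date, value)` of anomalies in percent.
#' @export
ndvi_anomaly <- function(dekads, baseline, daily = TRUE) {
  rainfall_anomaly(dekads, baseline, span = "dekad", daily = daily)
}

#' Expand a dekadal series to daily resolution
#'
#' Each calendar day takes the value of the dekad it belongs to (days 1-10,
#' 11-20, 21-end of month).
#'
#' @param dekadal Tibble `(area_id, date, value)` with `date` = dekad start.
#' @return A daily long tibble `(area_id, date, value)`.
#' @export
dekads_to_daily <- function(dekadal) {
  check_area_day(dekadal, "dekadal")
  dekadal |>
    group_by(area_id) |>
    reframe({
      ord <- order(date)
      starts <- date[ord]
      vals <- value[ord]
      ends <- c(starts[-1] - 1, dekad_end(starts[length(starts)]))
      lens <- as.integer(ends - starts + 1)
      tibble(date = rep(starts, lens) + sequence(lens) - 1, value = rep(vals, lens))
    }) |>
    ungroup()
}

dekad_end <- function(start) {
  day <- as.integer(format(start, "%d"))
  if (day < 21) {
    return(start + 9)
  }
  seq(as.Date(format(start, "%Y-%m-01")), by = "month", length.out = 2)[2] - 1
}

#' Ramadan day counter over the rolling window
#'
#' Counts, for each date `t`, how many days of the window `(t - d, t]` fall
#' inside a Ramadan observance interval. The counter ramps from 1 up to the
#' window/observance length during Ramadan, decays back after it ends, and
#' is zero during the rest of the year — mirroring how the consumption
#' measurements themselves aggregate the previous `d` days.
#'
#' @param dates Vector of dates to evaluate.
#' @param intervals Data frame with `start` and `end` dates of observances.
#' @param d Window length in days.
#' @return A tibble `(date, value)` of counts in `[0, d]`.
#' @examples
#' ramadan_counter(as.Date("2021-04-10") + 0:5,
#'   default_ramadan_intervals(),
#'   d = 7
#' )
#' @export
ramadan_counter <- function(dates, intervals = default_ramadan_intervals(),
                            d = 28) {
  check_number(d, "d", min = 1, integerish = TRUE)
  dates <- as_date_checked(dates, "dates")
  intervals <- as_tibble(intervals)
  if (any(intervals$end < intervals$start)) {
    stopf("`intervals` must satisfy start <= end.")
  }
  in_ramadan <- function(x) {
    out <- rep(FALSE, length(x))
    for (i in seq_len(nrow(intervals))) {
      out <- out | (x >= intervals$start[i] & x <= intervals$end[i])
    }
    out
  }
  value <- vapply(dates, function(t) {
    win <- seq(t - d + 1, t, by = "day")
    sum(in_ramadan(win))
  }, numeric(1))
  tibble(date = dates, value = value)
}

#' Greedy correlation pruning within a variable category
#'
#' Computes pairwise Pearson correlations (on pairwise-complete
#' observations) among candidate series of one category and, while any
#' surviving pair has `|r|` above the threshold, removes one variable of the
#' most-correlated pair — the one with the larger mean absolute correlation
#' to all other survivors, ties broken by name order. Constant series have
#' undefined correlations, which are treated as zero (with a warning).
#'
#' @param series_df Data frame whose numeric columns are the candidate
#'   series (rows aligned across series, e.g. dekads or days).
#' @param threshold Correlation magnitude above which a pair is collinear.
#' @return A list with `kept`, `dropped` (character vectors) and
#'   `correlations` (the full correlation matrix).
#' @examples
#' x <- rnorm(200)
#' correlation_prune(data.frame(a = x, b = x + rnorm(200, 0, 0.1), c = rnorm(200)))
#' @export
correlation_prune <- function(series_df, threshold = 0.45) {
  num <- series_df[vapply(series_df, is.numeric, logical(1))]
  if (ncol(num) < 2) stopf("need at least two numeric series to prune.")
  cm <- suppressWarnings(cor(num, use = "pairwise.complete.obs"))
  if (anyNA(cm)) {
    rlang::warn("undefined correlations (constant series?) treated as 0.")
    cm[is.na(cm)] <- 0
  }
  full <- cm
  kept <- colnames(cm)
  dropped <- character()
  repeat {
    sub <- abs(cm[kept, kept, drop = FALSE])
    diag(sub) <- 0
    if (length(kept) < 2 || max(sub) <= threshold) break
    idx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- sort(kept[idx])
    score <- rowMeans(sub[pair, setdiff(kept, pair), drop = FALSE])
    victim <- if (length(kept) == 2) {
      pair[2] # no outside neighbours: keep the alphabetically first
    } else if (abs(diff(score)) < 1e-12) pair[2] else pair[which.max(score)]
    dropped <- c(dropped, victim)
    kept <- setdiff(kept, victim)
  }
  list(kept = kept, dropped = dropped, correlations = full)
}

#' Variance inflation factors of a feature set
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` comes from the least-squares
#' regression of feature `j` on all other features. Values at or above the
#' flag threshold indicate multicollinearity; exactly collinear features get
#' an infinite VIF.
#'
#' @param feature_df Data frame of numeric features (more rows than
#'   columns; rows with any missing value are dropped).
#' @param flag_threshold VIF level at or above which a feature is flagged.
#' @return A tibble `(feature, vif, flagged)`.
#' @examples
#' vif_screen(data.frame(a = rnorm(100), b = rnorm(100)))
#' @export
vif_screen <- function(feature_df, flag_threshold = 3) {
  num <- feature_df[vapply(feature_df, is.numeric, logical(1))]
  if (ncol(num) < 2) stopf("need at least two features.")
  num <- num[complete.cases(num), , drop = FALSE]
  if (nrow(num) <= ncol(num)) stopf("need more complete rows than features.")
  vifs <- vapply(seq_along(num), function(j) {
    fit <- lm(num[[j]] ~ ., data = num[-j])
    # exact collinearity yields a perfect fit; the warning is the expected case
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble(
    feature = names(num), vif = vifs,
    flagged = vifs >= flag_threshold
  )
}
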