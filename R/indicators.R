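#' Compute the Food Consumption Score
#'
#' Weighted sum of the eight food-group frequencies. Vectorised: accepts one
#' frequency vector, a matrix with one row per household, or a data frame
#' carrying the `fg_*` columns written by [simulate_scenario()].
#'
#' @param food_freqs Numeric vector of length 8, an `n x 8` matrix, or a data
#'   frame with columns `fg_staples`, `fg_pulses`, `fg_vegetables`,
#'   `fg_fruit`, `fg_meat_fish`, `fg_milk`, `fg_sugar`, `fg_oil`. All values
#'   must be 7-day frequencies in `[0, 7]`.
#' @param scheme An [fcs_scheme()].
#' @return Numeric vector of FCS values, one per household.
#' @examples
#' compute_fcs(c(7, 2, 5, 1, 1, 0, 7, 7))
#' @export
compute_fcs <- function(food_freqs, scheme = fcs_scheme()) {
  stopifnot(inherits(scheme, "fcs_scheme"))
  m <- freq_matrix(food_freqs, paste0("fg_", fcs_food_groups), 8L, "food_freqs")
  as.numeric(m %*% scheme$group_weights)
}

#' Classify FCS values as poor / borderline / acceptable
#'
#' Poor if `score <= poor_threshold`, borderline if the score lies in
#' `(poor_threshold, borderline_threshold]`, acceptable above. Households
#' with poor or borderline consumption are the "insufficient food
#' consumption" class whose prevalence the pipeline forecasts.
#'
#' @param score Numeric FCS values.
#' @inheritParams compute_fcs
#' @return Factor with levels poor, borderline, acceptable.
#' @examples
#' classify_fcs(c(0, 21, 35, 35.5))
#' @export
classify_fcs <- function(score, scheme = fcs_scheme()) {
  stopifnot(inherits(scheme, "fcs_scheme"))
  if (any(score < 0, na.rm = TRUE)) stopf("FCS scores must be >= 0.")
  cut(score,
    breaks = c(-Inf, scheme$poor_threshold, scheme$borderline_threshold, Inf),
    labels = c("poor", "borderline", "acceptable")
  )
}

#' Compute the reduced Coping Strategy Index
#'
#' Severity-weighted sum of the five coping-behaviour frequencies, plus the
#' crisis flag (`score >= crisis_threshold`, inclusive).
#'
#' @param coping_freqs Numeric vector of length 5, an `n x 5` matrix, or a
#'   data frame with columns `cs_less_preferred`, `cs_borrow_food`,
#'   `cs_limit_portions`, `cs_restrict_adults`, `cs_reduce_meals`; values are
#'   7-day frequencies in `[0, 7]`.
#' @param scheme An [rcsi_scheme()].
#' @return A tibble with columns `rcsi` and `is_crisis`.
#' @examples
#' compute_rcsi(c(7, 7, 7, 7, 7))
#' @export
compute_rcsi <- function(coping_freqs, scheme = rcsi_scheme()) {
  stopifnot(inherits(scheme, "rcsi_scheme"))
  m <- freq_matrix(
    coping_freqs, paste0("cs_", rcsi_strategies), 5L, "coping_freqs"
  )
  score <- as.numeric(m %*% scheme$strategy_weights)
  tibble(rcsi = score, is_crisis = score >= scheme$crisis_threshold)
}

freq_matrix <- function(x, cols, n, name) {
  if (is.data.frame(x)) {
    missing_cols <- setdiff(cols, names(x))
    if (length(missing_cols) > 0) {
      stopf("`%s` is missing columns: %s.", name, toString(missing_cols))
    }
    x <- as.matrix(x[cols])
  } else if (!is.matrix(x)) {
    x <- matrix(x, ncol = n, byrow = TRUE)
  }
  check_freqs(x, n, name)
  x
}

#' Score and classify a table of household survey records
#'
#' Convenience layer over [compute_fcs()], [classify_fcs()] and
#' [compute_rcsi()]: appends `fcs`, `fcs_class`, `insufficient`, `rcsi` and
#' `rcsi_crisis` columns to a survey tibble.
#'
#' @param surveys Survey records in the schema of [simulate_scenario()].
#' @param fcs An [fcs_scheme()].
#' @param rcsi An [rcsi_scheme()].
#' @return The input tibble with scoring columns appended.
#' @export
score_surveys <- function(surveys, fcs = fcs_scheme(), rcsi = rcsi_scheme()) {
  score <- compute_fcs(surveys, fcs)
  cls <- classify_fcs(score, fcs)
  rc <- compute_rcsi(surveys, rcsi)
  surveys |>
    mutate(
      fcs = score,
      fcs_class = cls,
      insufficient = cls %in% c("poor", "borderline"),
      rcsi = rc$rcsi,
      rcsi_crisis = rc$is_crisis
    )
}

#' Daily prevalence via a weighted rolling window
#'
#' For each area and day `t`, the prevalence is the post-stratification
#' weighted share of flagged households among those interviewed during the
#' previous `d` days — the half-open window `(t - d, t]`, so interviews on
#' day `t` itself count. The household weight is the product
#' `weight_pop * weight_demo`. Days whose window contains no interviews are
#' returned as `NA` (fill them with [interpolate_gaps()]).
#'
#' @param surveys Survey tibble with `area_id`, `interview_date`,
#'   `weight_pop`, `weight_demo` and the frequency columns.
#' @param d Window length in days (>= 1).
#' @param indicator Which household flag drives the prevalence:
#'   `"fcs"` (poor-or-borderline food consumption, the target indicator) or
#'   `"rcsi"` (crisis-or-above coping, rCSI >= threshold).
#' @param fcs,rcsi Scoring schemes.
#' @param dates Optional date range (length-2) to fix the series support;
#'   defaults to the range of interview dates.
#' @return A long area-day tibble `(area_id, date, value)`, one row per area
#'   and calendar day, `value` in `[0, 1]` or `NA`.
#' @examples
#' s <- simulate_scenario(scenario_config(
#'   n_areas = 1, n_days = 40,
#'   households_per_day = 5, seed = 1
#' ))
#' rolling_prevalence(s$surveys, d = 7)
#' @export
rolling_prevalence <- function(surveys, d = 28,
                               indicator = c("fcs", "rcsi"),
                               fcs = fcs_scheme(), rcsi = rcsi_scheme(),
                               dates = NULL) {
  indicator <- match.arg(indicator)
  check_number(d, "d", min = 1, integerish = TRUE)
  if (nrow(surveys) == 0) {
    return(tibble(
      area_id = character(), date = as.Date(character()),
      value = numeric()
    ))
  }
  scored <- score_surveys(surveys, fcs, rcsi)
  flag <- if (indicator == "fcs") scored$insufficient else scored$rcsi_crisis
  w <- scored$weight_pop * scored$weight_demo
  if (any(w <= 0)) stopf("post-stratification weights must be positive.")
  daily <- tibble(
    area_id = scored$area_id,
    date = as.Date(scored$interview_date),
    w_num = w * flag,
    w_den = w
  ) |>
    group_by(area_id, date) |>
    summarise(w_num = sum(w_num), w_den = sum(w_den), .groups = "drop")

  rng <- if (is.null(dates)) range(daily$date) else as_date_checked(dates, "dates")
  all_days <- seq(rng[1], rng[2], by = "day")
  grid <- tidyr::expand_grid(
    area_id = sort(unique(daily$area_id)),
    date = all_days
  )
  full <- grid |>
    left_join(daily, by = c("area_id", "date")) |>
    mutate(
      w_num = tidyr::replace_na(w_num, 0),
      w_den = tidyr::replace_na(w_den, 0)
    ) |>
    group_by(area_id) |>
    arrange(date, .by_group = TRUE) |>
    mutate(
      num = roll_sum(w_num, d),
      den = roll_sum(w_den, d),
      value = ifelse(den > 0, num / den, NA_real_)
    ) |>
    ungroup()
  full |> select(area_id, date, value)
}

# trailing sum over the previous `d` entries (inclusive of the current one)
roll_sum <- function(x, d) {
  if (d >= length(x)) {
    return(cumsum_window(x, d))
  }
  as.numeric(stats::filter(x, rep(1, d), sides = 1)) |>
    (\(v) {
      v[seq_len(min(d - 1, length(x)))] <- cumsum(x)[seq_len(min(d - 1, length(x)))]
      v
    })()
}

cumsum_window <- function(x, d) cumsum(x)

#' Fill interior gaps of area-day series by linear interpolation
#'
#' Interior runs of `NA` are replaced by the straight line between the
#' nearest observed neighbours; leading and trailing `NA`s are left as-is
#' (interpolation is only defined between observations). Observed values are
#' never changed.
#'
#' @param series A long area-day tibble `(area_id, date, value)`.
#' @return The series with interior gaps filled.
#' @examples
#' s <- tibble::tibble(
#'   area_id = "A",
#'   date = as.Date("2020-01-01") + 0:2,
#'   value = c(0.2, NA, 0.4)
#' )
#' interpolate_gaps(s)
#' @export
interpolate_gaps <- function(series) {
  check_area_day(series)
  series |>
    group_by(area_id) |>
    arrange(date, .by_group = TRUE) |>
    mutate(value = {
      n_obs <- sum(!is.na(value))
      if (n_obs == 0) {
        stopf("area %s has no observed values to interpolate from.", area_id[1])
      }
      if (n_obs < 2) {
        stopf("area %s needs at least two observed values.", area_id[1])
      }
      zoo::na.approx(value, x = date, na.rm = FALSE)
    }) |>
    ungroup()
}

check_area_day <- function(series, name = "series") {
  need <- c("area_id", "date", "value")
  if (!is.data.frame(series) || !all(need %in% names(series))) {
    stopf("`%s` must be a data frame with columns area_id, date, value.", name)
  }
  invisible(series)
}
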