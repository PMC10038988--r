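#' Scenario configuration for the synthetic generator
#'
#' Defines a multi-area study scenario: its spatial/temporal extent, the
#' household sampling intensity, the rolling-window length `d` used to
#' aggregate surveys, and the dynamics of the latent prevalence of
#' insufficient food consumption. Defaults emulate a Yemen-like setting:
#' 20 first-level areas observed daily for 1340 days, prevalence mostly in
#' the 20-60% band, driven by conflict fatalities, rainfall anomalies,
#' market prices and Ramadan, on top of a slowly-mixing AR(1) component on
#' the logit scale.
#'
#' Driver effects enter the latent prevalence with a generator-side lag
#' (`driver_lags`, in days), so drivers observed today carry signal about
#' prevalence weeks ahead — the dependence structure a forecasting model can
#' exploit.
#'
#' @param n_areas Number of areas (>= 1).
#' @param n_days Length of the daily series (>= `rolling_window_d`).
#' @param start_date First day of the scenario.
#' @param households_per_day Interviews per area per day (>= 1).
#' @param rolling_window_d Rolling window `d` in days for prevalence
#'   aggregation (and for the fatality / Ramadan window features).
#' @param driver_coefficients Named logit-scale coefficients: `intercept`,
#'   `fatalities` (per unit of centred `log1p` of the `d`-day fatality sum),
#'   `rainfall_anomaly` (per unit of `anomaly/100 - 1`), `price` (per unit
#'   of log normalized price), `ramadan` (per unit of Ramadan-day share of
#'   the window), plus two optional nonlinear terms: `drought` (hinge on
#'   the rainfall deficit `max(0, 1 - anomaly/100)`; dry spells raise food
#'   insecurity, wet ones do not symmetrically lower it) and
#'   `conflict_price` (interaction of the centred log fatality sum with the
#'   positive part of log price: conflict hits harder when staples are
#'   expensive).
#' @param driver_lags Named lags (days) at which each driver affects the
#'   latent prevalence.
#' @param ar1_rho AR(1) coefficient of the latent logit noise, in `[0, 1)`.
#' @param noise_sd Innovation standard deviation of the AR(1) noise (>= 0).
#' @param area_effect_sd Standard deviation of static per-area logit offsets.
#' @param fatality_baseline_rate,fatality_burst_rate Daily Poisson rates of
#'   conflict fatalities outside/inside burst episodes.
#' @param burst_rate Daily probability of entering a burst episode.
#' @param burst_mean_duration Mean episode length in days (geometric).
#' @param rain_base,rain_amp Dekadal rainfall seasonal mean curve: base plus
#'   amplitude of the annual cycle, in mm per dekad.
#' @param rain_peak_dekad Dekad of year (1..36) at which rainfall peaks.
#' @param rain_shape Gamma shape of dekadal rainfall around its seasonal mean.
#' @param price_drift,price_sd Monthly drift and volatility of log prices.
#' @param price_jump_prob,price_jump_size Probability and mean log-size of
#'   upward price shocks.
#' @param markets_per_area Number of market price series per area.
#' @param ramadan_intervals Two-column data frame (`start`, `end`) of
#'   Ramadan observance periods; defaults cover 2018-2023.
#' @param crisis_prob Length-2 probabilities that a household uses
#'   crisis-level coping, given insufficient / acceptable food consumption.
#' @param weight_sdlog Log-sd of the lognormal post-stratification weights
#'   (mean 1 on the log scale); the weight law is a free design choice.
#' @param gap_fraction Fraction of area-days with no interviews (injected
#'   gaps exercising the linear interpolation), in `[0, 1)`.
#' @param fcs,rcsi Scoring schemes used to synthesise household frequency
#'   vectors consistent with each sampled class.
#' @param seed Global integer seed; every sub-stream derives from it.
#' @return An object of class `scenario_config`.
#' @examples
#' scenario_config(n_areas = 2, n_days = 100)
#' @export
scenario_config <- function(n_areas = 20,
                            n_days = 1340,
                            start_date = as.Date("2018-06-01"),
                            households_per_day = 25,
                            rolling_window_d = 28,
                            driver_coefficients = c(
                              intercept = -0.75, fatalities = 0.25,
                              rainfall_anomaly = -0.15, price = 0.45,
                              ramadan = -0.25, drought = 0.7,
                              conflict_price = 0.45
                            ),
                            driver_lags = c(
                              fatalities = 30, rainfall_anomaly = 60,
                              price = 30, ramadan = 0
                            ),
                            ar1_rho = 0.97,
                            noise_sd = 0.06,
                            area_effect_sd = 0.2,
                            fatality_baseline_rate = 0.5,
                            fatality_burst_rate = 15,
                            burst_rate = 0.01,
                            burst_mean_duration = 10,
                            rain_base = 8,
                            rain_amp = 55,
                            rain_peak_dekad = 22,
                            rain_shape = 2,
                            price_drift = 0.003,
                            price_sd = 0.04,
                            price_jump_prob = 0.05,
                            price_jump_size = 0.12,
                            markets_per_area = 2,
                            ramadan_intervals = default_ramadan_intervals(),
                            crisis_prob = c(0.7, 0.15),
                            weight_sdlog = 0.3,
                            gap_fraction = 0,
                            fcs = fcs_scheme(),
                            rcsi = rcsi_scheme(),
                            seed = 1) {
  check_number(n_areas, "n_areas", min = 1, integerish = TRUE)
  check_number(rolling_window_d, "rolling_window_d", min = 1, integerish = TRUE)
  check_number(n_days, "n_days", min = rolling_window_d, integerish = TRUE)
  check_number(households_per_day, "households_per_day", min = 1, integerish = TRUE)
  check_number(ar1_rho, "ar1_rho", min = 0, max = 1 - 1e-9)
  check_number(noise_sd, "noise_sd", min = 0)
  check_number(gap_fraction, "gap_fraction", min = 0, max = 1 - 1e-9)
  check_number(burst_rate, "burst_rate", min = 0, max = 1)
  check_number(seed, "seed", integerish = TRUE)
  need_coef <- c("intercept", "fatalities", "rainfall_anomaly", "price", "ramadan")
  if (!all(need_coef %in% names(driver_coefficients))) {
    stopf(
      "`driver_coefficients` must name: %s.",
      toString(setdiff(need_coef, names(driver_coefficients)))
    )
  }
  ramadan_intervals <- as_tibble(ramadan_intervals)
  if (!all(c("start", "end") %in% names(ramadan_intervals))) {
    stopf("`ramadan_intervals` must have columns start and end.")
  }
  ramadan_intervals$start <- as_date_checked(ramadan_intervals$start, "ramadan_intervals$start")
  ramadan_intervals$end <- as_date_checked(ramadan_intervals$end, "ramadan_intervals$end")
  if (any(ramadan_intervals$end < ramadan_intervals$start)) {
    stopf("`ramadan_intervals` must be well-ordered (start <= end).")
  }
  stopifnot(inherits(fcs, "fcs_scheme"), inherits(rcsi, "rcsi_scheme"))
  cfg <- as.list(environment())
  cfg$start_date <- as_date_checked(start_date, "start_date")
  cfg$need_coef <- NULL
  structure(cfg, class = "scenario_config")
}

#' Default Ramadan observance periods, 2018-2023
#'
#' Approximate Gregorian dates of Ramadan used by the synthetic calendar.
#' @return Tibble with columns `start`, `end`.
#' @export
default_ramadan_intervals <- function() {
  tibble(
    start = as.Date(c(
      "2018-05-16", "2019-05-06", "2020-04-24",
      "2021-04-13", "2022-04-02", "2023-03-23"
    )),
    end = as.Date(c(
      "2018-06-14", "2019-06-04", "2020-05-23",
      "2021-05-12", "2022-05-01", "2023-04-20"
    ))
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config> %d areas x %d days from %s; %d households/area-day; d = %d; seed = %d\n",
    x$n_areas, x$n_days, format(x$start_date), x$households_per_day,
    x$rolling_window_d, x$seed
  ))
  invisible(x)
}

area_ids <- function(config) sprintf("area_%02d", seq_len(config$n_areas))

scenario_dates <- function(config) {
  seq(config$start_date, by = "day", length.out = config$n_days)
}

# drivers are generated with a lead-in before start_date so that lagged
# driver values and trailing anomaly windows exist for every scenario day
driver_lead_days <- function(config) {
  max(config$driver_lags, 0) + 9 * 10 + config$rolling_window_d + 10
}

#' Generate synthetic driver data for a scenario
#'
#' Produces the driver bundle the forecasting features are built from:
#' episodic conflict fatalities (Poisson baseline plus geometric-duration
#' burst episodes with an elevated rate), seasonal dekadal rainfall (gamma
#' around a per-area seasonal mean curve), NDVI responding to recent
#' rainfall with a lag, monthly market prices following a positive random
#' walk with occasional upward shocks, the Ramadan calendar, and static area
#' attributes. All series start before `start_date` (a lead-in) so lagged
#' values exist from day one.
#'
#' @param config A [scenario_config()].
#' @return A list of class `driver_bundle` with elements `fatalities`,
#'   `rainfall` (list `dekads`, `baseline`), `ndvi` (same shape), `prices`,
#'   `ramadan_intervals`, `statics`, `dates`.
#' @examples
#' generate_drivers(scenario_config(n_areas = 2, n_days = 60))
#' @export
generate_drivers <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  areas <- area_ids(config)
  dates <- scenario_dates(config)
  lead <- driver_lead_days(config)
  full_dates <- seq(config$start_date - lead, max(dates), by = "day")

  fatalities <- with_seed(derive_seed(config$seed, "fatalities"), {
    purrr::map(areas, function(a) {
      n <- length(full_dates)
      # burst episodes: geometric durations at an elevated Poisson rate
      in_burst <- logical(n)
      i <- 1L
      while (i <= n) {
        if (config$burst_rate > 0 && runif(1) < config$burst_rate) {
          len <- rgeom(1, 1 / config$burst_mean_duration) + 1L
          in_burst[i:min(n, i + len - 1L)] <- TRUE
          i <- i + len
        } else {
          i <- i + 1L
        }
      }
      rate <- ifelse(in_burst, config$fatality_burst_rate, config$fatality_baseline_rate)
      tibble(area_id = a, date = full_dates, value = rpois(n, rate))
    }) |> purrr::list_rbind()
  })

  dekad_starts <- dekad_start_seq(min(full_dates), max(full_dates))
  doy <- dekad_of_year(dekad_starts)
  seasonal <- config$rain_base + config$rain_amp *
    (1 + cos(2 * pi * (doy - config$rain_peak_dekad) / 36)) / 2

  rain <- with_seed(derive_seed(config$seed, "rainfall"), {
    wet <- runif(length(areas), 0.7, 1.3) # per-area wetness multiplier
    dek <- purrr::map2(areas, wet, function(a, s) {
      mu <- seasonal * s
      tibble(
        area_id = a, date = dekad_starts, dekad = doy,
        value = rgamma(length(mu), shape = config$rain_shape, scale = mu / config$rain_shape)
      )
    }) |> purrr::list_rbind()
    base <- purrr::map2(areas, wet, function(a, s) {
      tibble(area_id = a, dekad = 1:36, mean = (config$rain_base + config$rain_amp *
        (1 + cos(2 * pi * (1:36 - config$rain_peak_dekad) / 36)) / 2) * s)
    }) |> purrr::list_rbind()
    list(dekads = dek, baseline = base)
  })

  ndvi <- with_seed(derive_seed(config$seed, "ndvi"), {
    dek <- rain$dekads |>
      group_by(area_id) |>
      arrange(date, .by_group = TRUE) |>
      mutate(
        # vegetation integrates the previous three dekads of rainfall
        wet3 = roll_sum(dplyr::lag(value, 1, default = 0), 3),
        value = pmin(1, pmax(
          -1,
          0.12 + 0.0018 * wet3 + rnorm(dplyr::n(), 0, 0.015)
        ))
      ) |>
      ungroup() |>
      select(area_id, date, dekad, value)
    base <- dek |>
      group_by(area_id, dekad) |>
      summarise(mean = mean(value), .groups = "drop")
    list(dekads = dek, baseline = base)
  })

  months <- seq(
    as.Date(format(min(full_dates), "%Y-%m-01")),
    as.Date(format(max(full_dates), "%Y-%m-01")),
    by = "month"
  )
  prices <- with_seed(derive_seed(config$seed, "prices"), {
    purrr::map(areas, function(a) {
      purrr::map(seq_len(config$markets_per_area), function(mkt) {
        n <- length(months)
        jumps <- rbinom(n, 1, config$price_jump_prob) *
          rexp(n, 1 / config$price_jump_size)
        lp <- log(100) + cumsum(config$price_drift + rnorm(n, 0, config$price_sd) + jumps)
        tibble(
          area_id = a, market_id = sprintf("%s_m%d", a, mkt),
          month = months, price = exp(lp)
        )
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })

  statics <- with_seed(derive_seed(config$seed, "statics"), {
    tibble(
      area_id = areas,
      population = round(rlnorm(length(areas), log(8e5), 0.6)),
      area_km2 = round(rlnorm(length(areas), log(9000), 0.5)),
      latitude = runif(length(areas), 12, 18),
      longitude = runif(length(areas), 43, 53),
      waterways = round(rlnorm(length(areas), log(120), 0.8))
    )
  })

  structure(
    list(
      fatalities = fatalities, rainfall = rain, ndvi = ndvi, prices = prices,
      ramadan_intervals = config$ramadan_intervals, statics = statics,
      dates = dates
    ),
    class = "driver_bundle"
  )
}

dekad_start_seq <- function(from, to) {
  months <- seq(as.Date(format(from, "%Y-%m-01")), as.Date(format(to, "%Y-%m-01")), by = "month")
  starts <- sort(c(months, months + 10, months + 20))
  starts[starts >= as.Date(format(from, "%Y-%m-01")) & starts <= to]
}

dekad_of_year <- function(dates) {
  m <- as.integer(format(dates, "%m"))
  day <- as.integer(format(dates, "%d"))
  (m - 1L) * 3L + pmin((day - 1L) %/% 10L + 1L, 3L)
}

#' Generate the latent daily prevalence of insufficient food consumption
#'
#' Combines lagged driver effects through a logistic link with a static
#' per-area offset and AR(1) noise on the logit scale. Drivers enter as:
#' centred `log1p` of the trailing `d`-day fatality sum; the 1-month
#' rainfall anomaly as `anomaly/100 - 1`; the log of the area's normalized
#' price; and the share of the `d`-day window covered by Ramadan. Each is
#' lagged by its configured `driver_lags` entry. Values are probabilities in
#' `[0, 1]`; under the default Yemen-like configuration the series stay
#' mostly within the 20-60% band.
#'
#' @param drivers A [generate_drivers()] bundle covering the scenario dates.
#' @param config The matching [scenario_config()].
#' @return A list of class `latent_prevalence`: `series` (long area-day
#'   tibble) and `components` (the logit-scale pieces, for diagnostics).
#' @export
generate_latent_prevalence <- function(drivers, config) {
  stopifnot(inherits(drivers, "driver_bundle"), inherits(config, "scenario_config"))
  dates <- scenario_dates(config)
  if (min(drivers$fatalities$date) > min(dates) - max(config$driver_lags)) {
    stopf("driver bundle does not cover the scenario date range (missing lead-in).")
  }
  areas <- area_ids(config)
  d <- config$rolling_window_d
  b <- config$driver_coefficients
  lags <- config$driver_lags

  fat_window <- aggregate_fatalities(drivers$fatalities, d = d)
  rain_anom <- rainfall_anomaly(
    drivers$rainfall$dekads, drivers$rainfall$baseline,
    span = "1-month"
  )
  price_daily <- monthly_price(drivers$prices, normalize = "first")
  ram <- ramadan_counter(
    seq(min(drivers$fatalities$date), max(dates), by = "day"),
    config$ramadan_intervals, d = d
  )

  center_fat <- log1p(d * config$fatality_baseline_rate)

  lag_value <- function(series, lag_days) {
    series |>
      mutate(date = date + lag_days) |>
      select(area_id, date, value)
  }

  grid <- tidyr::expand_grid(area_id = areas, date = dates) |>
    left_join(
      lag_value(fat_window, lags[["fatalities"]]) |> rename(fat = value),
      by = c("area_id", "date")
    ) |>
    left_join(
      lag_value(rain_anom, lags[["rainfall_anomaly"]]) |> rename(ra = value),
      by = c("area_id", "date")
    ) |>
    left_join(
      lag_value(price_daily, lags[["price"]]) |> rename(pr = value),
      by = c("area_id", "date")
    ) |>
    left_join(
      ram |> mutate(date = date + lags[["ramadan"]]) |> rename(rm = value),
      by = "date"
    )
  if (anyNA(grid[c("fat", "ra", "pr", "rm")])) {
    stopf("driver series do not align with the scenario dates (missing lagged values).")
  }

  area_eff <- with_seed(
    derive_seed(config$seed, "area_effects"),
    setNames(rnorm(length(areas), 0, config$area_effect_sd), areas)
  )
  noise <- with_seed(derive_seed(config$seed, "ar1_noise"), {
    purrr::map(areas, function(a) {
      n <- length(dates)
      z <- numeric(n)
      innov <- rnorm(n, 0, config$noise_sd)
      sd0 <- if (config$ar1_rho > 0) {
        config$noise_sd / sqrt(1 - config$ar1_rho^2)
      } else {
        config$noise_sd
      }
      z[1] <- rnorm(1, 0, sd0)
      for (t in seq_len(n)[-1]) z[t] <- config$ar1_rho * z[t - 1] + innov[t]
      tibble(area_id = a, date = dates, noise = z)
    }) |> purrr::list_rbind()
  })

  b_of <- function(nm) if (nm %in% names(b)) b[[nm]] else 0
  comp <- grid |>
    left_join(noise, by = c("area_id", "date")) |>
    mutate(
      eff_fat = b[["fatalities"]] * (log1p(fat) - center_fat),
      eff_rain = b[["rainfall_anomaly"]] * (ra / 100 - 1),
      eff_price = b[["price"]] * log(pmax(pr, 1e-9)),
      eff_ramadan = b[["ramadan"]] * (rm / d),
      # drought hinge: only rainfall deficits (not surpluses) raise
      # food insecurity
      eff_drought = b_of("drought") * pmax(0, 1 - ra / 100),
      # compounding shocks: conflict bites harder when prices are high
      eff_conflict_price = b_of("conflict_price") *
        (log1p(fat) - center_fat) * pmax(log(pmax(pr, 1e-9)), 0),
      logit = b[["intercept"]] + unname(area_eff[area_id]) +
        eff_fat + eff_rain + eff_price + eff_ramadan +
        eff_drought + eff_conflict_price + noise,
      value = stats::plogis(logit)
    )
  structure(
    list(
      series = comp |> select(area_id, date, value),
      components = comp |> select(-value)
    ),
    class = "latent_prevalence"
  )
}

#' Sample household survey records from a latent prevalence path
#'
#' For every area-day, draws `households_per_day` interview records. Each
#' household's insufficient-consumption class is Bernoulli on the latent
#' prevalence of that area-day; its eight food-group frequencies are then
#' drawn uniformly from the integer vectors whose FCS falls in the class
#' (rejection sampling under the configured scheme), so the class marginals
#' are exact by construction. Coping frequencies are drawn the same way
#' conditional on a crisis flag whose probability depends on the class,
#' coupling the rCSI prevalence to the latent path. Post-stratification
#' weights are lognormal with median 1. If `gap_fraction > 0`, that share
#' of area-days gets no interviews.
#'
#' @param latent A [generate_latent_prevalence()] result (or its `series`).
#' @param config The matching [scenario_config()].
#' @return A tibble of survey records: `area_id`, `interview_date`,
#'   `stratum`, `weight_pop`, `weight_demo`, eight `fg_*` and five `cs_*`
#'   frequency columns.
#' @export
sample_household_surveys <- function(latent, config) {
  stopifnot(inherits(config, "scenario_config"))
  series <- if (inherits(latent, "latent_prevalence")) latent$series else latent
  check_area_day(series)
  if (any(series$value < 0 | series$value > 1)) {
    stopf("latent prevalence values must lie in [0, 1].")
  }
  with_seed(derive_seed(config$seed, "surveys"), {
    keep <- rep(TRUE, nrow(series))
    if (config$gap_fraction > 0) {
      keep <- runif(nrow(series)) >= config$gap_fraction
    }
    obs <- series[keep, ]
    hh <- config$households_per_day
    n_tot <- nrow(obs) * hh
    rec <- tibble(
      area_id = rep(obs$area_id, each = hh),
      interview_date = rep(obs$date, each = hh),
      stratum = sample(c("urban", "rural", "displaced"), n_tot,
        replace = TRUE, prob = c(0.45, 0.45, 0.10)
      ),
      weight_pop = rlnorm(n_tot, 0, config$weight_sdlog),
      weight_demo = rlnorm(n_tot, 0, config$weight_sdlog),
      insufficient = runif(n_tot) < rep(obs$value, each = hh)
    )
    crisis <- runif(n_tot) < ifelse(
      rec$insufficient, config$crisis_prob[1], config$crisis_prob[2]
    )
    fg <- sample_class_freqs(
      rec$insufficient,
      n_groups = 8L,
      weights = config$fcs$group_weights,
      in_class = function(score, inside) {
        if (inside) {
          score <= config$fcs$borderline_threshold
        } else {
          score > config$fcs$borderline_threshold
        }
      }
    )
    colnames(fg) <- paste0("fg_", fcs_food_groups)
    cs <- sample_class_freqs(
      crisis,
      n_groups = 5L,
      weights = config$rcsi$strategy_weights,
      in_class = function(score, inside) {
        if (inside) {
          score >= config$rcsi$crisis_threshold
        } else {
          score < config$rcsi$crisis_threshold
        }
      }
    )
    colnames(cs) <- paste0("cs_", rcsi_strategies)
    bind_cols(rec |> select(-insufficient), as_tibble(fg), as_tibble(cs))
  })
}

# Draw, for each element of `flag`, a frequency vector uniform over the
# integer vectors {0..7}^n whose weighted score satisfies the class
# predicate. Batch rejection, vectorised over households.
sample_class_freqs <- function(flag, n_groups, weights, in_class) {
  n <- length(flag)
  out <- matrix(NA_integer_, n, n_groups)
  for (inside in c(TRUE, FALSE)) {
    idx <- which(flag == inside)
    need <- length(idx)
    if (need == 0) next
    got <- 0L
    acc <- matrix(NA_integer_, need, n_groups)
    while (got < need) {
      batch <- max(1000L, ceiling((need - got) * 3))
      draw <- matrix(
        sample.int(8L, batch * n_groups, replace = TRUE) - 1L,
        batch, n_groups
      )
      score <- as.numeric(draw %*% weights)
      ok <- which(in_class(score, inside))
      take <- head(ok, need - got)
      if (length(take) > 0) {
        acc[(got + 1):(got + length(take)), ] <- draw[take, , drop = FALSE]
        got <- got + length(take)
      }
    }
    out[idx, ] <- acc
  }
  out
}

#' Simulate a complete scenario
#'
#' Runs [generate_drivers()], [generate_latent_prevalence()] and
#' [sample_household_surveys()] for one configuration. Identical
#' configurations (including seed) give bitwise-identical output.
#'
#' @param config A [scenario_config()].
#' @return A list of class `scenario`: `config`, `drivers`, `latent`
#'   (area-day tibble of true prevalences), `surveys`.
#' @examples
#' sc <- simulate_scenario(scenario_config(
#'   n_areas = 2, n_days = 60,
#'   households_per_day = 5
#' ))
#' names(sc)
#' @export
simulate_scenario <- function(config = scenario_config()) {
  drivers <- generate_drivers(config)
  latent <- generate_latent_prevalence(drivers, config)
  surveys <- sample_household_surveys(latent, config)
  structure(
    list(
      config = config, drivers = drivers,
      latent = latent$series, surveys = surveys
    ),
    class = "scenario"
  )
}
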