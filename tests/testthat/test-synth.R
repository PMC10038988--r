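cfg_small <- function(...) {
  args <- utils::modifyList(
    list(n_areas = 2, n_days = 120, households_per_day = 8, seed = 7),
    list(...)
  )
  do.call(scenario_config, args)
}

test_that("identical configurations reproduce bitwise-identical scenarios", {
  a <- simulate_scenario(cfg_small())
  b <- simulate_scenario(cfg_small())
  expect_identical(a$surveys, b$surveys)
  expect_identical(a$latent, b$latent)
  expect_identical(a$drivers$fatalities, b$drivers$fatalities)
  expect_identical(a$drivers$prices, b$drivers$prices)
  # a different seed changes the draw
  c <- simulate_scenario(cfg_small(seed = 8))
  expect_false(identical(a$surveys, c$surveys))
})

test_that("zero burst rate leaves fatalities at the baseline Poisson law", {
  cfg <- cfg_small(
    burst_rate = 0, fatality_baseline_rate = 0.5, n_days = 1000
  )
  f <- generate_drivers(cfg)$fatalities
  # Poisson(0.5): mean within Monte-Carlo error, no burst-level outliers
  expect_lt(abs(mean(f$value) - 0.5), 3 * sqrt(0.5 / nrow(f)))
  expect_lt(max(f$value), 8)
})

test_that("rainfall reproduces its configured seasonal mean curve", {
  # 100 simulated years of dekads vs. the configured per-area baseline
  cfg <- scenario_config(
    n_areas = 1, n_days = 36500, households_per_day = 1, seed = 21
  )
  dr <- generate_drivers(cfg)
  obs <- dr$rainfall$dekads |>
    dplyr::mutate(dekad = foodcast:::dekad_of_year(date)) |>
    dplyr::group_by(dekad) |>
    dplyr::summarise(m = mean(value), se = sd(value) / sqrt(dplyr::n()))
  joined <- dplyr::left_join(obs, dr$rainfall$baseline, by = "dekad")
  expect_true(all(abs(joined$m - joined$mean) <= 3 * joined$se))
})

test_that("degenerate coefficients give a constant logistic prevalence", {
  cfg <- cfg_small(
    driver_coefficients = c(
      intercept = -0.3, fatalities = 0,
      rainfall_anomaly = 0, price = 0, ramadan = 0
    ),
    ar1_rho = 0, noise_sd = 0, area_effect_sd = 0
  )
  lat <- generate_latent_prevalence(generate_drivers(cfg), cfg)
  expect_equal(unique(lat$series$value), plogis(-0.3), tolerance = 1e-12)
})

test_that("a positive fatality coefficient couples prevalence to lagged conflict", {
  cfg <- scenario_config(
    n_areas = 1, n_days = 2000, households_per_day = 1,
    driver_coefficients = c(
      intercept = -0.5, fatalities = 0.5,
      rainfall_anomaly = 0, price = 0, ramadan = 0
    ),
    ar1_rho = 0, noise_sd = 0.02, seed = 33
  )
  dr <- generate_drivers(cfg)
  lat <- generate_latent_prevalence(dr, cfg)
  fat <- aggregate_fatalities(dr$fatalities, d = cfg$rolling_window_d) |>
    dplyr::mutate(date = date + cfg$driver_lags[["fatalities"]])
  j <- dplyr::inner_join(lat$series, fat, by = c("area_id", "date"))
  expect_gt(cor(j$value.x, log1p(j$value.y)), 0)
})

test_that("with rho = 0 the AR(1) noise component is serially uncorrelated", {
  cfg <- scenario_config(
    n_areas = 1, n_days = 4000, households_per_day = 1,
    ar1_rho = 0, noise_sd = 0.3, seed = 13
  )
  lat <- generate_latent_prevalence(generate_drivers(cfg), cfg)
  z <- lat$components$noise
  r1 <- cor(z[-1], z[-length(z)])
  expect_lt(abs(r1), 3 / sqrt(length(z)))
})

test_that("household classes follow the latent prevalence exactly at the margins", {
  cfg <- cfg_small(n_days = 30)
  dates <- seq(cfg$start_date, by = "day", length.out = cfg$n_days)
  flat <- function(p) {
    tidyr::expand_grid(area_id = c("area_01", "area_02"), date = dates) |>
      dplyr::mutate(value = p)
  }
  s0 <- sample_household_surveys(flat(0), cfg) |> score_surveys()
  expect_true(all(s0$fcs_class == "acceptable"))
  s1 <- sample_household_surveys(flat(1), cfg) |> score_surveys()
  expect_true(all(s1$fcs_class %in% c("poor", "borderline")))
})

test_that("the insufficient share is binomial around the latent value", {
  cfg <- scenario_config(
    n_areas = 1, n_days = 10, households_per_day = 1000,
    rolling_window_d = 7, seed = 5
  )
  dates <- seq(cfg$start_date, by = "day", length.out = 10)
  lat <- tibble::tibble(area_id = "area_01", date = dates, value = 0.4)
  s <- sample_household_surveys(lat, cfg) |> score_surveys()
  share <- mean(s$fcs_class %in% c("poor", "borderline"))
  se <- sqrt(0.4 * 0.6 / nrow(s))
  expect_lt(abs(share - 0.4), 3 * se)
})

test_that("the default scenario keeps prevalence in its working band", {
  cfg <- scenario_config(seed = 11)
  lat <- generate_latent_prevalence(generate_drivers(cfg), cfg)
  v <- lat$series$value
  expect_true(all(v >= 0 & v <= 1))
  expect_gte(mean(v >= 0.15 & v <= 0.65), 0.9)
})

test_that("gap injection removes area-days and interpolation bridges them", {
  cfg <- cfg_small(gap_fraction = 0.2)
  sc <- simulate_scenario(cfg)
  n_expected <- cfg$n_areas * cfg$n_days
  n_got <- nrow(dplyr::distinct(
    sc$surveys, area_id, interview_date
  ))
  expect_lt(n_got, n_expected)
  prev <- rolling_prevalence(sc$surveys, d = 3) |> interpolate_gaps()
  inner <- prev |>
    dplyr::group_by(area_id) |>
    dplyr::filter(date >= min(date[!is.na(value)]), date <= max(date[!is.na(value)]))
  expect_false(anyNA(inner$value))
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(scenario_config(n_areas = 0), "n_areas")
  expect_error(scenario_config(n_days = 10, rolling_window_d = 28), "n_days")
  expect_error(scenario_config(ar1_rho = 1), "ar1_rho")
  expect_error(scenario_config(noise_sd = -1), "noise_sd")
  expect_error(
    scenario_config(ramadan_intervals = data.frame(
      start = as.Date("2020-05-01"), end = as.Date("2020-04-01")
    )),
    "well-ordered"
  )
})
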