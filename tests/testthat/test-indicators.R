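test_that("FCS is the weighted sum of food-group frequencies", {
  expect_equal(compute_fcs(rep(0, 8)), 0)
  # staples weight 2 under the default scheme
  expect_equal(compute_fcs(c(7, 0, 0, 0, 0, 0, 0, 0)), 14)
  # hand-summed: 7*2 + 2*3 + 5*1 + 1*1 + 1*4 + 0*4 + 7*0.5 + 7*0.5 = 37
  expect_equal(compute_fcs(c(7, 2, 5, 1, 1, 0, 7, 7)), 37.0)
  # vectorised over a matrix
  m <- rbind(rep(0, 8), c(7, 2, 5, 1, 1, 0, 7, 7))
  expect_equal(compute_fcs(m), c(0, 37))
  expect_error(compute_fcs(c(8, rep(0, 7))), "\\[0, 7\\]")
  expect_error(compute_fcs(c(-1, rep(0, 7))), "\\[0, 7\\]")
})

test_that("FCS classification uses inclusive upper bounds", {
  sch <- fcs_scheme()
  expect_equal(as.character(classify_fcs(0, sch)), "poor")
  expect_equal(as.character(classify_fcs(21, sch)), "poor")
  expect_equal(as.character(classify_fcs(21.01, sch)), "borderline")
  expect_equal(as.character(classify_fcs(35, sch)), "borderline")
  expect_equal(as.character(classify_fcs(35.01, sch)), "acceptable")
  expect_error(classify_fcs(-1, sch), ">= 0")
})

test_that("rCSI scoring and the inclusive crisis threshold", {
  r0 <- compute_rcsi(rep(0, 5))
  expect_equal(r0$rcsi, 0)
  expect_false(r0$is_crisis)
  # all-7 frequencies: 7 * (1+2+1+3+1) = 56
  r7 <- compute_rcsi(rep(7, 5))
  expect_equal(r7$rcsi, 56)
  expect_true(r7$is_crisis)
  # a score of exactly 19 is crisis (threshold inclusive)
  r19 <- compute_rcsi(c(7, 3, 6, 0, 0)) # 7 + 6 + 6 = 19
  expect_equal(r19$rcsi, 19)
  expect_true(r19$is_crisis)
  r18 <- compute_rcsi(c(7, 3, 5, 0, 0))
  expect_false(r18$is_crisis)
})

test_that("rolling prevalence is the weighted share over the previous d days", {
  day <- as.Date("2021-03-10")
  s <- make_survey_rows("A", day, c(TRUE, FALSE))
  prev <- rolling_prevalence(s, d = 7)
  expect_equal(prev$value[prev$date == day], 0.5)
  # weight 3 on the poor household
  s2 <- make_survey_rows("A", day, c(TRUE, FALSE), w_pop = c(3, 1))
  prev2 <- rolling_prevalence(s2, d = 7)
  expect_equal(prev2$value[prev2$date == day], 0.75)
  # day t's interviews count toward day t; they drop out after d days
  s3 <- make_survey_rows("A", day, TRUE)
  prev3 <- rolling_prevalence(s3, d = 3, dates = c(day, day + 5))
  expect_equal(prev3$value, c(1, 1, 1, NA, NA, NA))
})

test_that("rolling prevalence matches the brute-force weighted share", {
  set.seed(88)
  days <- as.Date("2020-06-01") + 0:39
  s <- make_survey_rows(
    sample(c("A", "B"), 120, replace = TRUE),
    sample(days, 120, replace = TRUE),
    runif(120) < 0.4,
    w_pop = rlnorm(120, 0, 0.5),
    w_demo = rlnorm(120, 0, 0.5)
  )
  for (d in c(1, 7, 28)) {
    got <- rolling_prevalence(s, d = d, dates = range(days))
    want <- brute_rolling_prevalence(s, d = d, days)
    expect_equal(got$value, want$value, tolerance = 1e-12)
  }
})

test_that("prevalence is bounded and invariant to weight rescaling", {
  set.seed(99)
  days <- as.Date("2020-06-01") + 0:19
  s <- make_survey_rows(
    "A", sample(days, 60, replace = TRUE), runif(60) < 0.5,
    w_pop = runif(60, 0.2, 3), w_demo = runif(60, 0.2, 3)
  )
  p1 <- rolling_prevalence(s, d = 10)
  expect_true(all(p1$value >= 0 & p1$value <= 1, na.rm = TRUE))
  s2 <- s |> dplyr::mutate(weight_pop = weight_pop * 17.3)
  p2 <- rolling_prevalence(s2, d = 10)
  expect_equal(p1$value, p2$value, tolerance = 1e-12)
})

test_that("linear interpolation fills interior gaps only", {
  mk <- function(v) {
    tibble::tibble(
      area_id = "A",
      date = as.Date("2020-01-01") + seq_along(v) - 1, value = v
    )
  }
  expect_equal(interpolate_gaps(mk(c(0.2, NA, 0.4)))$value, c(0.2, 0.3, 0.4))
  expect_equal(
    interpolate_gaps(mk(c(0.1, NA, NA, 0.4)))$value,
    c(0.1, 0.2, 0.3, 0.4)
  )
  # no gaps: identity
  expect_equal(interpolate_gaps(mk(c(0.1, 0.2, 0.3)))$value, c(0.1, 0.2, 0.3))
  # leading/trailing gaps are not extrapolated
  out <- interpolate_gaps(mk(c(NA, 0.2, NA, 0.4, NA)))
  expect_equal(out$value, c(NA, 0.2, 0.3, 0.4, NA))
  expect_error(interpolate_gaps(mk(c(NA, NA, NA))), "no observed")
  expect_error(interpolate_gaps(mk(c(NA, 0.3, NA))), "at least two")
})

test_that("prevalence estimates recover the latent path at the binomial rate", {
  # same latent path, increasing daily sample size -> shrinking RMSE
  base <- scenario_config(
    n_areas = 1, n_days = 120, households_per_day = 15,
    driver_coefficients = c(
      intercept = -0.4, fatalities = 0, rainfall_anomaly = 0,
      price = 0, ramadan = 0
    ),
    ar1_rho = 0.9, noise_sd = 0.05, seed = 314
  )
  dr <- generate_drivers(base)
  lat <- generate_latent_prevalence(dr, base)
  rmse_at <- function(hh) {
    cfg <- base
    cfg$households_per_day <- hh
    s <- sample_household_surveys(lat, cfg)
    est <- rolling_prevalence(s, d = base$rolling_window_d)
    # compare to the window-average latent (what the estimator targets)
    truth <- lat$series |>
      dplyr::arrange(date) |>
      dplyr::mutate(
        cs = cumsum(value),
        wsum = cs - dplyr::lag(cs, 28, default = 0),
        navg = pmin(dplyr::row_number(), 28),
        truth = wsum / navg
      )
    keep <- est$date >= min(est$date) + 28
    sqrt(mean((est$value[keep] - truth$truth[keep])^2, na.rm = TRUE))
  }
  expect_lt(rmse_at(150), rmse_at(15))
})
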