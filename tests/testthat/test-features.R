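test_that("fatality aggregation sums events over the trailing d-day window", {
  rng <- as.Date(c("2021-01-01", "2021-01-20"))
  none <- tibble::tibble(
    area_id = "A", date = as.Date("2021-01-05"), value = 0
  )
  z <- aggregate_fatalities(none, d = 7, dates = rng)
  expect_true(all(z$value == 0))
  # one event of 5 fatalities shows up on exactly d consecutive days
  ev <- tibble::tibble(area_id = "A", date = as.Date("2021-01-05"), value = 5)
  agg <- aggregate_fatalities(ev, d = 7, dates = rng)
  expect_equal(sum(agg$value == 5), 7)
  expect_equal(
    agg$date[agg$value == 5],
    seq(as.Date("2021-01-05"), as.Date("2021-01-11"), by = "day")
  )
  # two events inside one window add up
  ev2 <- dplyr::bind_rows(ev, tibble::tibble(
    area_id = "A", date = as.Date("2021-01-07"), value = 2
  ))
  agg2 <- aggregate_fatalities(ev2, d = 7, dates = rng)
  expect_equal(agg2$value[agg2$date == as.Date("2021-01-08")], 7)
})

test_that("market prices normalize per market and average across markets", {
  months <- seq(as.Date("2021-01-01"), by = "month", length.out = 3)
  p <- tibble::tibble(
    area_id = "A",
    market_id = rep(c("m1", "m2"), each = 3),
    month = rep(months, 2),
    price = c(100, 100, 100, 200, 200, 200)
  )
  out <- monthly_price(p, normalize = "first", daily = FALSE)
  expect_equal(out$value, rep(1, 3))
  out_m <- monthly_price(p, normalize = "mean", daily = FALSE)
  expect_equal(out_m$value, rep(1, 3))
  # single market: the normalized series itself
  single <- monthly_price(p |> dplyr::filter(market_id == "m1"),
    normalize = "first", daily = FALSE
  )
  expect_equal(single$value, c(1, 1, 1))
  # daily expansion carries each month value through its days
  daily <- monthly_price(p, normalize = "first")
  expect_equal(nrow(daily), 31 + 28 + 31)
  expect_error(monthly_price(p |> dplyr::mutate(price = -price)), "> 0")
})

test_that("rainfall anomaly uses the percent-of-average convention", {
  dekads <- tibble::tibble(
    area_id = "A",
    date = foodcast:::dekad_start_seq(as.Date("2021-01-01"), as.Date("2021-06-30")),
  ) |> dplyr::mutate(value = 20)
  baseline <- tibble::tibble(area_id = "A", dekad = 1:36, mean = 20)
  a <- rainfall_anomaly(dekads, baseline, span = "1-month", daily = FALSE)
  expect_equal(a$value, rep(100, nrow(a)))
  a2 <- rainfall_anomaly(
    dekads |> dplyr::mutate(value = 40), baseline,
    span = "1-month", daily = FALSE
  )
  expect_equal(a2$value, rep(200, nrow(a2)))
  # hand case: trailing dekads (10, 20, 30) against baseline (20, 20, 20)
  dek3 <- dekads
  dek3$value <- rep_len(c(10, 20, 30), nrow(dek3))
  a3 <- rainfall_anomaly(dek3, baseline, span = "1-month", daily = FALSE)
  expect_equal(a3$value[3], 100 * 60 / 60)
})

test_that("NDVI anomaly is the single-dekad ratio and matches brute force", {
  set.seed(10)
  dekads <- tibble::tibble(
    area_id = "A",
    date = foodcast:::dekad_start_seq(as.Date("2021-01-01"), as.Date("2021-12-31"))
  ) |> dplyr::mutate(value = runif(dplyr::n(), 0.1, 0.6))
  baseline <- tibble::tibble(area_id = "A", dekad = 1:36, mean = runif(36, 0.2, 0.5))
  got <- ndvi_anomaly(dekads, baseline, daily = FALSE)
  want <- 100 * dekads$value /
    baseline$mean[foodcast:::dekad_of_year(dekads$date)]
  expect_equal(got$value, want, tolerance = 1e-12)
  expect_equal(
    ndvi_anomaly(
      dekads |> dplyr::mutate(value = 0.5 * baseline$mean[foodcast:::dekad_of_year(date)]),
      baseline,
      daily = FALSE
    )$value,
    rep(50, nrow(dekads))
  )
})

test_that("the Ramadan counter tracks window overlap with observance days", {
  iv <- tibble::tibble(
    start = as.Date("2021-04-13"), end = as.Date("2021-05-12")
  )
  # three days into Ramadan with a 7-day window
  expect_equal(
    ramadan_counter(as.Date("2021-04-15"), iv, d = 7)$value, 3
  )
  # last Ramadan day with a window at least as long as the observance
  expect_equal(
    ramadan_counter(as.Date("2021-05-12"), iv, d = 40)$value, 30
  )
  # more than d days after the end: back to zero
  expect_equal(
    ramadan_counter(as.Date("2021-06-30"), iv, d = 28)$value, 0
  )
  # decay right after the end
  expect_equal(
    ramadan_counter(as.Date("2021-05-19"), iv, d = 28)$value, 21
  )
})

test_that("correlation pruning drops one of each collinear pair", {
  set.seed(3)
  x <- rnorm(1000)
  dup <- data.frame(a = x, b = x)
  out <- correlation_prune(dup)
  expect_equal(length(out$kept), 1)
  expect_equal(length(out$dropped), 1)
  # independent noise survives
  noise <- data.frame(a = rnorm(1000), b = rnorm(1000))
  out2 <- correlation_prune(noise)
  expect_equal(sort(out2$kept), c("a", "b"))
  # r(A,B) = 0.9, both nearly uncorrelated with C: exactly one of A/B goes
  n <- 2000
  A <- rnorm(n)
  B <- 0.9 * A + sqrt(1 - 0.81) * rnorm(n)
  C <- rnorm(n)
  out3 <- correlation_prune(data.frame(A = A, B = B, C = C))
  expect_true("C" %in% out3$kept)
  expect_equal(length(out3$kept), 2)
  expect_equal(length(intersect(out3$dropped, c("A", "B"))), 1)
  # idempotence: pruning the kept set changes nothing
  out4 <- correlation_prune(data.frame(A = A, B = B, C = C)[out3$kept])
  expect_equal(sort(out4$kept), sort(out3$kept))
  expect_equal(out4$dropped, character(0))
})

test_that("VIF matches its closed form", {
  set.seed(4)
  n <- 500
  # columns orthogonal to each other and to the intercept -> VIF 1
  q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4]
  v <- vif_screen(as.data.frame(q))
  expect_equal(v$vif, rep(1, 3), tolerance = 1e-10)
  expect_false(any(v$flagged))
  # duplicated feature -> unbounded, flagged
  d <- data.frame(a = rnorm(n))
  d$b <- d$a
  d$c <- rnorm(n)
  v2 <- vif_screen(d)
  expect_true(all(v2$flagged[v2$feature %in% c("a", "b")]))
  expect_true(all(is.infinite(v2$vif[v2$feature %in% c("a", "b")])))
  # R^2 = 0.5 against the others -> VIF = 2
  z <- rnorm(n)
  w <- z + rnorm(n, 0, sd = 1) # R^2 = var(z)/var(w) = 0.5 in expectation
  v3 <- vif_screen(data.frame(z = z, w = w))
  r2 <- summary(lm(w ~ z))$r.squared
  expect_equal(v3$vif[v3$feature == "w"], 1 / (1 - r2), tolerance = 1e-10)
})

test_that("design features only use information up to the reference date", {
  asm <- small_design()
  design <- asm$design
  rows <- design_rows(design, 1)
  # lag-0 target feature equals the prevalence at the reference date itself
  j <- dplyr::inner_join(
    rows |> dplyr::select(area_id, ref_date, target_lag0),
    asm$prevalence_fcs |> dplyr::rename(ref_date = date),
    by = c("area_id", "ref_date")
  )
  expect_equal(j$target_lag0, j$value, tolerance = 1e-12)
  # the target column is the prevalence h days ahead
  j2 <- dplyr::inner_join(
    design_rows(design, 7) |>
      dplyr::mutate(date = ref_date + 7) |>
      dplyr::select(area_id, date, target),
    asm$prevalence_fcs,
    by = c("area_id", "date")
  )
  expect_equal(j2$target, j2$value, tolerance = 1e-12)
})

test_that("corrupting future driver values never touches earlier design rows", {
  sc <- small_scenario()
  cut <- min(sc$latent$date) + 250
  corrupt <- function(s) {
    s |> dplyr::mutate(value = ifelse(date >= cut, 999, value))
  }
  prev <- rolling_prevalence(sc$surveys, d = sc$config$rolling_window_d) |>
    interpolate_gaps()
  fat <- aggregate_fatalities(sc$drivers$fatalities, d = 28)
  d1 <- build_design(prev,
    drivers = list(fat = fat),
    lags = list(target = c(0, 7), driver = c(0, 14)), horizons = 7
  )
  d2 <- build_design(prev,
    drivers = list(fat = corrupt(fat)),
    lags = list(target = c(0, 7), driver = c(0, 14)), horizons = 7
  )
  r1 <- design_rows(d1, 7) |> dplyr::filter(ref_date < cut)
  r2 <- design_rows(d2, 7) |> dplyr::filter(ref_date < cut)
  expect_identical(r1, r2)
})

test_that("design row counts follow the counting formula", {
  sc <- small_scenario()
  prev <- rolling_prevalence(sc$surveys, d = sc$config$rolling_window_d) |>
    interpolate_gaps()
  design <- build_design(prev, horizons = c(1, 15))
  n_areas <- length(unique(prev$area_id))
  n_days <- length(unique(prev$date))
  for (h in c(1, 15)) {
    # one row per area per reference date whose target day is observed
    expect_equal(nrow(design_rows(design, h)), n_areas * (n_days - h))
  }
})
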