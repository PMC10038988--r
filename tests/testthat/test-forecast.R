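test_that("monthly splits are disjoint, time-ordered, and leak-free", {
  design <- small_design()$design
  sp <- make_splits(design, k = 3)
  expect_equal(nrow(sp), 3)
  expect_true(all(diff(sp$test_start) > 0))
  for (i in seq_len(3)) {
    expect_equal(
      sp$test_end[i],
      seq(sp$test_start[i], by = "month", length.out = 2)[2] - 1
    )
    if (i > 1) expect_equal(sp$test_start[i], sp$test_end[i - 1] + 1)
  }
  # k = 1: single holdout = last complete month
  sp1 <- make_splits(design, k = 1)
  expect_equal(nrow(sp1), 1)
  expect_equal(sp1$test_end[1], max(sp$test_end))
  expect_error(
    make_splits(design, k = 12),
    "too short"
  )
})

test_that("training rows never reach into the test window", {
  design <- small_design()$design
  sp <- make_splits(design, k = 2)
  for (i in 1:2) {
    for (h in c(1, 14)) {
      rows <- design_rows(design, h) |>
        dplyr::filter(target_date < sp$test_start[i])
      expect_lt(max(rows$target_date), sp$test_start[i])
      expect_lte(max(rows$ref_date) + h, sp$test_start[i] - 1 + h)
    }
  }
})

test_that("the naive forecast is persistence, identical across horizons", {
  s <- tibble::tibble(
    area_id = "A", date = as.Date("2021-01-01") + 0:9,
    value = c(0.3, 0.35, 0.4, 0.42, NA, NA, 0.42, 0.41, 0.42, NA)
  )
  nf <- naive_forecast(s, as.Date("2021-01-10"), horizons = 1:30)
  expect_equal(nrow(nf), 30)
  expect_equal(unique(nf$pred), 0.42) # last observed value
  # constant series: zero error at every horizon
  cs <- tibble::tibble(
    area_id = "A", date = as.Date("2021-01-01") + 0:9, value = 0.5
  )
  nfc <- naive_forecast(cs, as.Date("2021-01-08"), horizons = c(1, 30))
  expect_equal(nfc$pred, c(0.5, 0.5))
  expect_error(
    naive_forecast(s, as.Date("2020-12-01")),
    "no observed value"
  )
})

test_that("a single grid candidate is selected and fitting is deterministic", {
  design <- small_design()$design
  sp <- make_splits(design, k = 1)
  fit1 <- fit_horizon_models(design, sp,
    horizons = c(1, 7), grid = tiny_grid(),
    seed = 42, nrounds_max = 40
  )
  expect_equal(sort(names(fit1$models)), c("1", "7"))
  expect_equal(unique(tidy(fit1)$candidate), 1)
  fit2 <- fit_horizon_models(design, sp,
    horizons = c(1, 7), grid = tiny_grid(),
    seed = 42, nrounds_max = 40
  )
  p1 <- predict_paths(fit1, design)
  p2 <- predict_paths(fit2, design)
  expect_identical(p1, p2)
  # predictions: one path of each horizon per area, clipped to [0, 1]
  expect_equal(nrow(p1), 2 * length(unique(design$features$area_id)))
  expect_true(all(p1$pred >= 0 & p1$pred <= 1))
})

test_that("an exactly learnable target is learned to near-zero validation error", {
  # target = linear function of its own lag-0 value
  set.seed(31)
  days <- as.Date("2020-01-01") + 0:699
  base <- tibble::tibble(
    area_id = "A", date = days,
    value = 0.4 + 0.25 * sin(seq_along(days) / 25)
  )
  design <- build_design(base, lags = list(target = 0:3), horizons = 1)
  sp <- make_splits(design, k = 1)
  fit <- fit_horizon_models(design, sp,
    horizons = 1,
    grid = tibble::tibble(max_depth = 5L, eta = 0.3, subsample = 1.0),
    seed = 3, nrounds_max = 400, early_stopping_rounds = 50
  )
  val_mse <- tidy(fit)$val_rmse^2
  expect_lt(val_mse, 0.01 * var(base$value))
})

test_that("different seeds change subsampled fits, same seed never does", {
  design <- small_design()$design
  sp <- make_splits(design, k = 1)
  g <- tibble::tibble(max_depth = 3L, eta = 0.1, subsample = 0.7)
  fa <- fit_horizon_models(design, sp, horizons = 1, grid = g, seed = 1, nrounds_max = 30)
  fb <- fit_horizon_models(design, sp, horizons = 1, grid = g, seed = 2, nrounds_max = 30)
  fc <- fit_horizon_models(design, sp, horizons = 1, grid = g, seed = 1, nrounds_max = 30)
  pa <- predict_paths(fa, design)$pred
  pb <- predict_paths(fb, design)$pred
  pc <- predict_paths(fc, design)$pred
  expect_identical(pa, pc)
  expect_false(identical(pa, pb))
})

test_that("horizon models are independent of each other's rows", {
  design <- small_design()$design
  sp <- make_splits(design, k = 1)
  # fitting h = 7 alone or together with h = 1 gives the same h = 7 model
  both <- fit_horizon_models(design, sp,
    horizons = c(1, 7),
    grid = tiny_grid(), seed = 5, nrounds_max = 30
  )
  alone <- fit_horizon_models(design, sp,
    horizons = 7,
    grid = tiny_grid(), seed = 5, nrounds_max = 30
  )
  pb <- predict_paths(both, design) |> dplyr::filter(horizon == 7)
  pa <- predict_paths(alone, design)
  expect_equal(pb$pred, pa$pred)
})

test_that("rows with missing features are still predicted", {
  design <- small_design()$design
  sp <- make_splits(design, k = 1)
  fit <- fit_horizon_models(design, sp,
    horizons = 1, grid = tiny_grid(),
    seed = 8, nrounds_max = 20
  )
  # earliest reference dates have missing long-lag features by construction
  early <- min(design$features$ref_date)
  p <- predict_paths(fit, design, ref_dates = early)
  expect_true(all(is.finite(p$pred)))
})
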