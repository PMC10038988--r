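# Independent brute-force oracles and shared small fixtures.

# ordinal patterns by sorting every window independently; ties broken by
# temporal order via rank(ties.method = "first")
brute_ordinal_counts <- function(x, m, tau = 1) {
  n_w <- length(x) - (m - 1) * tau
  keys <- vapply(seq_len(n_w), function(i) {
    w <- x[i + (0:(m - 1)) * tau]
    paste(rank(w, ties.method = "first"), collapse = "-")
  }, character(1))
  tab <- table(keys)
  tibble::tibble(pattern = names(tab), count = as.integer(tab))
}

brute_entropy <- function(x, m, tau = 1, normalized = TRUE) {
  cnt <- brute_ordinal_counts(x, m, tau)$count
  p <- cnt / sum(cnt)
  h <- -sum(p * log(p))
  if (normalized) h / log(factorial(m)) else h
}

# weighted share of insufficient households interviewed in (t-d, t],
# recomputed per day from the raw records
brute_rolling_prevalence <- function(surveys, d, dates_grid) {
  scored <- foodcast::score_surveys(surveys)
  w <- scored$weight_pop * scored$weight_demo
  out <- list()
  for (a in sort(unique(scored$area_id))) {
    in_a <- scored$area_id == a
    vals <- vapply(seq_along(dates_grid), function(i) {
      t <- dates_grid[i]
      sel <- in_a & scored$interview_date > t - d & scored$interview_date <= t
      if (!any(sel)) {
        return(NA_real_)
      }
      sum(w[sel] * scored$insufficient[sel]) / sum(w[sel])
    }, numeric(1))
    out[[a]] <- tibble::tibble(area_id = a, date = dates_grid, value = vals)
  }
  dplyr::bind_rows(out)
}

# tiny survey table with explicit classes: `poor` rows get all-zero food
# frequencies (FCS 0), `acceptable` rows get everything at 7 (FCS 112)
make_survey_rows <- function(area_id, date, insufficient, w_pop = 1, w_demo = 1) {
  n <- length(insufficient)
  fg <- matrix(0L, n, 8)
  fg[!insufficient, ] <- 7L
  colnames(fg) <- paste0("fg_", c(
    "staples", "pulses", "vegetables", "fruit",
    "meat_fish", "milk", "sugar", "oil"
  ))
  cs <- matrix(0L, n, 5)
  colnames(cs) <- paste0("cs_", c(
    "less_preferred", "borrow_food", "limit_portions",
    "restrict_adults", "reduce_meals"
  ))
  dplyr::bind_cols(
    tibble::tibble(
      area_id = rep_len(area_id, n),
      interview_date = rep_len(as.Date(date), n),
      stratum = "any",
      weight_pop = rep_len(w_pop, n),
      weight_demo = rep_len(w_demo, n)
    ),
    tibble::as_tibble(fg), tibble::as_tibble(cs)
  )
}

# small driver-coupled scenario shared by several forecast tests; built once
small_scenario_cache <- new.env(parent = emptyenv())
small_scenario <- function() {
  if (is.null(small_scenario_cache$sc)) {
    cfg <- scenario_config(
      n_areas = 5, n_days = 400, households_per_day = 10, seed = 271
    )
    small_scenario_cache$sc <- simulate_scenario(cfg)
  }
  small_scenario_cache$sc
}

small_design_cache <- new.env(parent = emptyenv())
small_design <- function() {
  if (is.null(small_design_cache$asm)) {
    small_design_cache$asm <- assemble_design(small_scenario(), horizons = c(1, 7, 14))
  }
  small_design_cache$asm
}

tiny_grid <- function() tibble::tibble(max_depth = 3L, eta = 0.1, subsample = 1.0)
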