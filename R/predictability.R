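#' Ordinal pattern distribution of a time series
#'
#' Slides a window of `m` values spaced `tau` apart along the series and maps
#' each window to the permutation that sorts it ascending (Bandt-Pompe
#' symbolisation). Ties are broken by temporal order, i.e. the earlier of two
#' equal values ranks lower, which keeps the mapping deterministic. The
#' resulting motif counts are the basis of the permutation entropy.
#'
#' @param series Numeric vector, length at least `(m - 1) * tau + 1`.
#' @param m Embedding dimension (window length), 2..7.
#' @param tau Time delay between window elements; 1 uses consecutive days.
#' @return A tibble of class `ordinal_distribution` with columns `pattern`
#'   (permutation as a dash-separated rank string) and `count`, plus
#'   attributes `m`, `tau` and `n_windows`.
#' @examples
#' ordinal_patterns(c(4, 7, 9, 10, 6, 11, 3), m = 3)
#' @export
ordinal_patterns <- function(series, m = 3, tau = 1) {
  check_number(m, "m", min = 2, max = 7, integerish = TRUE)
  check_number(tau, "tau", min = 1, integerish = TRUE)
  if (anyNA(series)) stopf("`series` must not contain missing values.")
  n <- length(series)
  need <- (m - 1) * tau + 1
  if (n < need) {
    stopf(
      "series of length %d is too short: m = %d, tau = %d needs at least %d values.",
      n, m, tau, need
    )
  }
  ids <- pattern_ids(series, m, tau)
  tab <- tabulate(ids + 1L, nbins = factorial(m))
  keep <- which(tab > 0L)
  out <- tibble(
    pattern = pattern_labels(m)[keep],
    count = as.integer(tab[keep])
  )
  structure(out,
    m = as.integer(m), tau = as.integer(tau),
    n_windows = length(ids),
    class = c("ordinal_distribution", class(out))
  )
}

# Integer id in [0, m!-1] of the sorting permutation of every window.
# rank of element j within its window = #(k: x_k < x_j) + #(k < j: x_k == x_j);
# the id is the mixed-radix encoding of those ranks (Lehmer-style), computed
# fully vectorised across windows.
pattern_ids <- function(series, m, tau) {
  n_w <- length(series) - (m - 1) * tau
  w <- vapply(
    seq_len(m),
    function(j) series[seq_len(n_w) + (j - 1L) * tau],
    numeric(n_w)
  )
  if (n_w == 1L) w <- matrix(w, nrow = 1L)
  ranks <- matrix(0L, n_w, m)
  for (j in seq_len(m)) {
    for (k in seq_len(m)) {
      if (k == j) next
      lt <- w[, k] < w[, j]
      if (k < j) lt <- lt | (w[, k] == w[, j])
      ranks[, j] <- ranks[, j] + lt
    }
  }
  id <- integer(n_w)
  for (j in seq_len(m)) id <- id * m + ranks[, j]
  # compress mixed-radix code to a dense 0..m!-1 id via lookup
  match(id, sort(unique(all_pattern_codes(m)))) - 1L
}

# codes of all m! permutations under the same encoding, in lexicographic
# order of the rank sequence
all_pattern_codes <- function(m) {
  perms <- permutations_of(m)
  apply(perms, 1L, function(r) {
    id <- 0L
    for (j in seq_len(m)) id <- id * m + (r[j] - 1L)
    id
  })
}

pattern_labels <- function(m) {
  perms <- permutations_of(m)
  codes <- apply(perms, 1L, function(r) {
    id <- 0L
    for (j in seq_len(m)) id <- id * m + (r[j] - 1L)
    id
  })
  labs <- apply(perms, 1L, paste, collapse = "-")
  labs[order(codes)]
}

permutations_of <- function(m) {
  if (m == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- permutations_of(m - 1L)
  out <- matrix(0L, nrow(sub) * m, m)
  row <- 1L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(m)) {
      out[row, ] <- append(sub[i, ], m, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

#' Permutation entropy of an ordinal pattern distribution
#'
#' Shannon entropy `H = -sum p log p` over the motif probabilities
#' `p = count / n_windows`, with `0 log 0 = 0`. With `normalized = TRUE`
#' (default) the entropy is divided by `log(m!)` so `H` lies in `[0, 1]`;
#' natural logarithms are used (the base cancels under normalisation).
#'
#' @param dist An [ordinal_patterns()] result.
#' @param normalized Divide by `log(m!)`?
#' @return A single entropy value.
#' @examples
#' permutation_entropy(ordinal_patterns(1:10, m = 3)) # 0: one motif only
#' @export
permutation_entropy <- function(dist, normalized = TRUE) {
  if (!inherits(dist, "ordinal_distribution")) {
    stopf("`dist` must come from ordinal_patterns().")
  }
  n <- attr(dist, "n_windows")
  if (is.null(n) || n < 1) stopf("empty ordinal distribution.")
  p <- dist$count / n
  p <- p[p > 0]
  h <- -sum(p * log(p))
  if (normalized) h <- h / log(factorial(attr(dist, "m")))
  h
}

#' Predictability from normalized permutation entropy
#'
#' `chi = 1 - H`: 1 for a fully regular (deterministic) series, 0 for one
#' whose motifs are uniformly random.
#'
#' @param h_normalized Normalized permutation entropy in `[0, 1]`.
#' @return `1 - h_normalized`.
#' @export
predictability <- function(h_normalized) {
  if (any(h_normalized < -1e-12 | h_normalized > 1 + 1e-12, na.rm = TRUE)) {
    stopf("`h_normalized` must lie in [0, 1]; normalise the entropy first.")
  }
  1 - pmin(pmax(h_normalized, 0), 1)
}

#' Windowed predictability profile of area-day series
#'
#' For each window length `L` in `window_lengths`, draws `n_samples` random
#' window start points per area series (uniformly, without replacement when
#' enough starts exist), computes the normalized permutation entropy of each
#' window, and aggregates `chi = 1 - H` across all windows and areas: mean
#' and interquartile range per window length. This profiles how
#' predictability decays as longer stretches of history are considered.
#'
#' @param series A long area-day tibble `(area_id, date, value)` with no
#'   missing values, or a plain numeric vector (treated as one area).
#' @param window_lengths Integer window lengths, default 10..100 days.
#' @param n_samples Random start points per area and window length.
#' @param m,tau Embedding dimension and delay for the ordinal patterns.
#' @param seed Integer seed for the start-point sampling.
#' @return A tibble of class `predictability_curve`: `window_length`,
#'   `mean_chi`, `q25`, `q75`, `n_windows`.
#' @examples
#' x <- sin(seq(0, 20, length.out = 300)) + rnorm(300, 0, 0.05)
#' predictability_profile(x, window_lengths = c(10, 50), n_samples = 50, seed = 1)
#' @export
predictability_profile <- function(series, window_lengths = 10:100,
                                   n_samples = 1000, m = 3, tau = 1,
                                   seed = 1) {
  check_number(m, "m", min = 2, max = 7, integerish = TRUE)
  if (is.numeric(series)) {
    series <- tibble(
      area_id = "series",
      date = as.Date("2000-01-01") + seq_along(series) - 1,
      value = as.numeric(series)
    )
  }
  check_area_day(series)
  if (anyNA(series$value)) {
    stopf("`series` has missing values; interpolate_gaps() first.")
  }
  window_lengths <- sort(unique(as.integer(window_lengths)))
  if (any(window_lengths < (m - 1) * tau + 2)) {
    stopf("window lengths must exceed the embedding span (m - 1) * tau + 1.")
  }
  if (factorial(m) > min(window_lengths) - (m - 1) * tau) {
    # guard: more possible motifs than windows -> entropy badly under-sampled
    rlang::warn("m! exceeds the number of patterns in the smallest window; entropy estimates will be strongly biased.")
  }
  by_area <- split(series$value, series$area_id)
  too_short <- vapply(by_area, length, 1L) <= max(window_lengths)
  if (any(too_short)) {
    stopf(
      "series for area(s) %s are not longer than the largest window (%d).",
      toString(names(by_area)[too_short]), max(window_lengths)
    )
  }
  mfac <- factorial(m)
  rows <- with_seed(derive_seed(seed, "predictability_profile"), {
    purrr::map(by_area, function(x) {
      ids <- pattern_ids(x, m, tau) + 1L
      # cumulative motif counts allow O(1) per-window tabulation
      cum <- apply(
        vapply(seq_len(mfac), function(k) ids == k, logical(length(ids))),
        2L, cumsum
      )
      cum <- rbind(0, cum)
      purrr::map(window_lengths, function(L) {
        n_pat <- L - (m - 1) * tau # patterns per window of length L
        n_start <- length(x) - L + 1
        starts <- if (n_start >= n_samples) {
          sample.int(n_start, n_samples)
        } else {
          sample.int(n_start, n_samples, replace = TRUE)
        }
        counts <- cum[starts + n_pat, , drop = FALSE] -
          cum[starts, , drop = FALSE]
        p <- counts / n_pat
        hl <- p * log(p)
        hl[!is.finite(hl)] <- 0
        h <- -rowSums(hl) / log(mfac)
        tibble(window_length = L, chi = 1 - h)
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })
  out <- rows |>
    group_by(window_length = .data$window_length) |>
    summarise(
      mean_chi = mean(.data$chi),
      q25 = quantile(.data$chi, 0.25, names = FALSE),
      q75 = quantile(.data$chi, 0.75, names = FALSE),
      n_windows = dplyr::n(),
      .groups = "drop"
    )
  class(out) <- c("predictability_curve", class(out))
  attr(out, "m") <- as.integer(m)
  attr(out, "tau") <- as.integer(tau)
  out
}
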