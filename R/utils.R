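# Internal helpers: validation and seed-stream derivation.

stopf <- function(fmt, ...) rlang::abort(sprintf(fmt, ...))

check_number <- function(x, name, min = -Inf, max = Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stopf("`%s` must be a single non-missing number.", name)
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    stopf("`%s` must be a whole number.", name)
  }
  if (x < min || x > max) {
    stopf("`%s` must be in [%s, %s], got %s.", name, min, max, x)
  }
  invisible(x)
}

check_freqs <- function(x, n, name) {
  if (!is.numeric(x)) stopf("`%s` must be numeric.", name)
  if (is.matrix(x)) {
    if (ncol(x) != n) stopf("`%s` must have %d columns.", name, n)
  } else if (length(x) %% n != 0L) {
    stopf("`%s` must have length a multiple of %d.", name, n)
  }
  if (anyNA(x) || any(x < 0) || any(x > 7)) {
    stopf("`%s` must contain 7-day frequencies in [0, 7].", name)
  }
  invisible(x)
}

# Derive a reproducible sub-seed for a named sub-stream from one global seed.
# Keeps values well inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  check_number(seed, "seed", integerish = TRUE)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(as.numeric(seed)) * 1009 + h * 31) %% 2147483587)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

as_date_checked <- function(x, name) {
  d <- tryCatch(as.Date(x), error = function(e) NA)
  if (anyNA(d)) stopf("`%s` must be coercible to Date.", name)
  d
}
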