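#' Food Consumption Score scoring scheme
#'
#' The FCS is a weighted sum of 7-day consumption frequencies over eight food
#' groups (staples, pulses, vegetables, fruit, meat/fish, milk, sugar, oil),
#' each weighted by nutritional value. Thresholds split households into
#' poor / borderline / acceptable consumption; "insufficient" means poor or
#' borderline. Weights and thresholds follow standard WFP practice and are
#' fully configurable per country.
#'
#' @param group_weights Positive weights for the eight food groups, in the
#'   order staples, pulses, vegetables, fruit, meat_fish, milk, sugar, oil.
#' @param poor_threshold Scores `<=` this value are labelled poor.
#' @param borderline_threshold Scores in `(poor_threshold,
#'   borderline_threshold]` are labelled borderline; above it, acceptable.
#' @return An object of class `fcs_scheme`.
#' @examples
#' fcs_scheme()
#' @export
fcs_scheme <- function(group_weights = c(
                         staples = 2, pulses = 3, vegetables = 1, fruit = 1,
                         meat_fish = 4, milk = 4, sugar = 0.5, oil = 0.5
                       ),
                       poor_threshold = 21, borderline_threshold = 35) {
  if (length(group_weights) != 8L || any(group_weights <= 0)) {
    stopf("`group_weights` must be 8 positive weights.")
  }
  check_number(poor_threshold, "poor_threshold", min = 0)
  check_number(borderline_threshold, "borderline_threshold", min = 0)
  if (poor_threshold >= borderline_threshold) {
    stopf("`poor_threshold` must be below `borderline_threshold`.")
  }
  if (is.null(names(group_weights))) {
    names(group_weights) <- fcs_food_groups
  }
  structure(
    list(
      group_weights = group_weights,
      poor_threshold = poor_threshold,
      borderline_threshold = borderline_threshold
    ),
    class = "fcs_scheme"
  )
}

fcs_food_groups <- c(
  "staples", "pulses", "vegetables", "fruit",
  "meat_fish", "milk", "sugar", "oil"
)

rcsi_strategies <- c(
  "less_preferred", "borrow_food", "limit_portions",
  "restrict_adults", "reduce_meals"
)

#' Reduced Coping Strategy Index scoring scheme
#'
#' The rCSI is a severity-weighted sum of the 7-day frequencies of five
#' food-based coping behaviours (relying on less preferred food, borrowing
#' food, limiting portion sizes, restricting adult consumption, reducing the
#' number of meals). Households with rCSI at or above the crisis threshold
#' (19 by convention) are using crisis-or-above coping.
#'
#' @param strategy_weights Positive severity weights for the five strategies.
#' @param crisis_threshold Scores `>=` this value flag crisis-level coping.
#' @return An object of class `rcsi_scheme`.
#' @examples
#' rcsi_scheme()
#' @export
rcsi_scheme <- function(strategy_weights = c(
                          less_preferred = 1, borrow_food = 2,
                          limit_portions = 1, restrict_adults = 3,
                          reduce_meals = 1
                        ),
                        crisis_threshold = 19) {
  if (length(strategy_weights) != 5L || any(strategy_weights <= 0)) {
    stopf("`strategy_weights` must be 5 positive weights.")
  }
  check_number(crisis_threshold, "crisis_threshold", min = 1e-12)
  if (is.null(names(strategy_weights))) {
    names(strategy_weights) <- rcsi_strategies
  }
  structure(
    list(
      strategy_weights = strategy_weights,
      crisis_threshold = crisis_threshold
    ),
    class = "rcsi_scheme"
  )
}

#' @export
print.fcs_scheme <- function(x, ...) {
  cat("<fcs_scheme>\n")
  cat("  weights:", paste(names(x$group_weights), x$group_weights,
    sep = "=", collapse = ", "
  ), "\n")
  cat(
    "  poor <=", x$poor_threshold, "< borderline <=",
    x$borderline_threshold, "< acceptable\n"
  )
  invisible(x)
}

#' @export
print.rcsi_scheme <- function(x, ...) {
  cat("<rcsi_scheme>\n")
  cat("  weights:", paste(names(x$strategy_weights), x$strategy_weights,
    sep = "=", collapse = ", "
  ), "\n")
  cat("  crisis at score >=", x$crisis_threshold, "\n")
  invisible(x)
}
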