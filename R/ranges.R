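# Lognormal fatality-range probabilities and emergency-response levels.

# response-level ranges: (0,10] -> IV, (10,50] -> III, (50,300] -> II,
# (300, Inf) -> I
.neep_lower <- c(0, 10, 50, 300)
.neep_upper <- c(10, 50, 300, Inf)
.neep_levels <- c("IV", "III", "II", "I")
.neep_names <- c("0-10", "10-50", "50-300", ">300")

#' Emergency-response fatality ranges
#'
#' The four national emergency-response tiers keyed to fatality counts:
#' level IV (<= 10 fatalities), III (10-50], II (50-300], I (> 300).
#'
#' @return data frame with columns `level`, `lower`, `upper`.
#' @export
neep_ranges <- function() {
  data.frame(level = .neep_levels, lower = .neep_lower, upper = .neep_upper,
             row.names = .neep_names)
}

#' Probability that fatalities fall in a range
#'
#' Fatalities are modelled as lognormal about the estimate `E` with log
#' scale `zeta` (the fit's log residual):
#' `P(a < fatalities <= b) = Phi[(ln b - ln E)/zeta] - Phi[(ln a - ln E)/zeta]`,
#' with `ln 0 = -Inf` (term 0) and `ln Inf = +Inf` (term 1).  At `b = E` the
#' upper term is exactly 1/2: `E` is the median of the lognormal.
#'
#' @param E expected fatalities, `> 0`.
#' @param zeta lognormal log scale, `> 0`.
#' @param a,b range bounds, `0 <= a < b <= Inf`.
#' @return probability in \[0, 1\].
#' @examples
#' range_probability(5, 1.774, 0, 10)
#' @export
range_probability <- function(E, zeta, a, b) {
  if (!is.finite(E) || E <= 0) stop("E must be > 0", call. = FALSE)
  if (!is.finite(zeta) || zeta <= 0) stop("zeta must be > 0", call. = FALSE)
  if (a < 0 || a >= b) stop("need 0 <= a < b", call. = FALSE)
  up <- if (is.infinite(b)) 1 else pnorm((log(b) - log(E)) / zeta)
  lo <- if (a == 0) 0 else pnorm((log(a) - log(E)) / zeta)
  up - lo
}

#' Construct a fatality estimate report
#'
#' Bundles the expected count, its rounded value, the four range
#' probabilities and the response level.  The level is the range with the
#' largest probability.  For `expected == 0` (no exposed population at
#' damaging intensity) the lognormal is undefined and the convention is
#' `P(0-10] = 1`, level IV.
#'
#' @param expected expected fatalities, `>= 0`.
#' @param zeta lognormal log scale (`> 0`; may be omitted when
#'   `expected == 0`).
#' @return object of class `fatality_estimate` with fields `expected`,
#'   `rounded`, `range_probs`, `level`, `zeta`.
#' @export
fatality_estimate <- function(expected, zeta = NULL) {
  if (!is.finite(expected) || expected < 0)
    stop("expected must be a non-negative number", call. = FALSE)
  if (expected == 0) {
    probs <- setNames(c(1, 0, 0, 0), .neep_names)
    level <- "IV"
    zeta <- zeta %||% NA_real_
  } else {
    if (is.null(zeta)) stop("zeta required when expected > 0", call. = FALSE)
    probs <- vapply(seq_along(.neep_lower), function(i)
      range_probability(expected, zeta, .neep_lower[i], .neep_upper[i]),
      numeric(1))
    names(probs) <- .neep_names
    level <- .neep_levels[which.max(probs)]
  }
  structure(list(expected = expected, rounded = round_half_up(expected),
                 range_probs = probs, level = level, zeta = zeta),
            class = "fatality_estimate")
}

#' Range probabilities and response level for an estimate
#'
#' Evaluates [range_probability()] on the four response-level ranges; the
#' probabilities partition (0, Inf) and sum to one.
#'
#' @inheritParams range_probability
#' @return a [fatality_estimate()] object.
#' @examples
#' level_probabilities(5, 1.774)    # level IV, P(0-10) ~ 0.652
#' level_probabilities(104, 1.774)  # level II
#' @export
level_probabilities <- function(E, zeta) {
  if (!is.finite(E) || E <= 0) stop("E must be > 0", call. = FALSE)
  fatality_estimate(E, zeta)
}

#' @export
print.fatality_estimate <- function(x, ...) {
  cat("Fatality estimate\n")
  cat(sprintf("  expected: %.3f (reported: %d)\n", x$expected,
              as.integer(x$rounded)))
  cat(sprintf("  response level: %s\n", x$level))
  cat("  range probabilities:\n")
  for (i in seq_along(x$range_probs))
    cat(sprintf("    %-7s (level %-3s): %5.1f%%\n", names(x$range_probs)[i],
                .neep_levels[i], 100 * x$range_probs[i]))
  invisible(x)
}
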