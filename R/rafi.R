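#' Reciprocal allonursing frequency index (RAFI)
#'
#' RAFI measures how evenly two mothers match one another's allonursing.
#' For an unordered dyad \{A, B\} with `a_ab` bouts given by A to B's
#' offspring and `a_ba` bouts given by B to A's offspring,
#' \deqn{RAFI = 1 - \left| \frac{a_{AB}}{a_A + a_B} - \frac{a_{BA}}{a_A + a_B} \right|}
#' where \eqn{a_A + a_B = a_{AB} + a_{BA}} is the dyad's total. The index
#' ranges from 0 (strictly one-sided helping) to 1 (complete reciprocation)
#' and is undefined (`NA`) when the dyad exchanged no allonursing at all.
#'
#' @param a_ab,a_ba Nonnegative integer counts of allonursing bouts in the
#'   two directions of the dyad. Recycled to common length.
#' @return Numeric vector in `[0, 1]`, `NA` where both counts are zero.
#' @examples
#' rafi(3, 3)  # 1: complete reciprocation
#' rafi(5, 0)  # 0: unidirectional
#' rafi(3, 1)  # 0.5
#' @export
rafi <- function(a_ab, a_ba) {
  if (any(a_ab < 0, na.rm = TRUE) || any(a_ba < 0, na.rm = TRUE)) {
    stop("allonursing counts must be nonnegative")
  }
  tot <- a_ab + a_ba
  out <- 1 - abs(a_ab / tot - a_ba / tot)
  out[tot == 0] <- NA_real_
  out
}

#' Classify a RAFI value against the reciprocity interpretation thresholds
#'
#' Values below 0.5 indicate a tendency towards unidirectional helping,
#' values of 0.5 or more a tendency towards reciprocity, and values of 0.8
#' or more strong reciprocity.
#'
#' @param value Numeric vector of RAFI values in `[0, 1]` (`NA` allowed for
#'   undefined dyads).
#' @return Character vector with levels `"unidirectional_tendency"`,
#'   `"reciprocal_tendency"`, `"strong_reciprocity"`; `NA` for undefined input.
#' @export
classify_rafi <- function(value) {
  if (any(value < 0 | value > 1, na.rm = TRUE)) {
    stop("RAFI values must lie in [0, 1]")
  }
  out <- rep(NA_character_, length(value))
  out[!is.na(value) & value < 0.5] <- "unidirectional_tendency"
  out[!is.na(value) & value >= 0.5] <- "reciprocal_tendency"
  out[!is.na(value) & value >= 0.8] <- "strong_reciprocity"
  out
}

#' Convert RAFI to the integer count scale used by the RAFI response models
#'
#' Multiplies by 100 and rounds to the nearest integer (half away from
#' zero), giving a count in `0..100` suitable as a Poisson/negative-binomial
#' response.
#'
#' @param value Numeric vector of RAFI values in `[0, 1]`.
#' @return Integer vector in `0..100`; `NA` where the index is undefined.
#' @export
rafi_to_count <- function(value) {
  if (any(value < 0 | value > 1, na.rm = TRUE)) {
    stop("RAFI values must lie in [0, 1]")
  }
  as.integer(round_half_up(100 * value))
}
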