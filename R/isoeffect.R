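#' Round half away from zero
#'
#' The table-printing convention used throughout: 42.857 -> 42.9 at one
#' decimal place, 82.5 -> 83 at zero. Base `round()` rounds half to even
#' and would not reproduce the printed tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return `x` rounded half away from zero.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Biologically effective dose (BED)
#'
#' `BED = n * d * (1 + d / ratio)` for a schedule of `n` fractions of
#' `d` Gy at linear-quadratic ratio `alpha/beta = ratio` (Gy). Equal BED
#' implies isoeffect under the LQ model. No time/repopulation factor is
#' included.
#'
#' @param n Number of fractions (`>= 1`, vectorised).
#' @param d Dose per fraction, Gy (`>= 0`, vectorised).
#' @param ratio Alpha/beta ratio, Gy (`> 0`, vectorised).
#' @return BED in Gy.
#' @examples
#' bed(n = 10, d = 2, ratio = 1.75) # 42.857
#' @export
bed <- function(n, d, ratio) {
  check_ratio(ratio)
  if (any(n < 1) || any(d < 0)) {
    stop("need n >= 1 and d >= 0", call. = FALSE)
  }
  n * d * (1 + d / ratio)
}

#' Equivalent total dose in 2 Gy fractions (EQD2)
#'
#' `EQD2 = BED / (1 + 2 / ratio)`: the total dose that, delivered in
#' conventional 2 Gy fractions, carries the same BED.
#'
#' @param bed_gy BED in Gy (`>= 0`, vectorised).
#' @param ratio Alpha/beta ratio, Gy (`> 0`).
#' @return EQD2 in Gy.
#' @examples
#' eqd2(42.857, 1.75) # 20
#' @export
eqd2 <- function(bed_gy, ratio) {
  check_ratio(ratio)
  if (any(bed_gy < 0)) stop("BED must be >= 0", call. = FALSE)
  bed_gy / (1 + 2 / ratio)
}

#' Isoeffective dose per fraction for a new schedule
#'
#' Solves the BED isoeffect equality
#' `n2 * d2 * (1 + d2 / ratio) = n1 * d1 * (1 + d1 / ratio)` for `d2`.
#' The quadratic in `d2` has a single non-negative root,
#' `d2 = (ratio / 2) * (-1 + sqrt(1 + 4 * BED / (n2 * ratio)))`.
#' With `n2 = 1` this is the "calculated" equivalent single dose for a
#' fractionated regimen.
#'
#' @param n1,d1 Source schedule: fractions and dose per fraction (Gy).
#' @param n2 Fraction count of the target schedule (`>= 1`).
#' @param ratio Alpha/beta ratio, Gy (`> 0`).
#' @return Dose per fraction `d2` of the isoeffective target schedule, Gy.
#' @examples
#' equivalent_dose_per_fraction(n1 = 2, d1 = 4, n2 = 1, ratio = 1.75) # 5.96
#' @export
equivalent_dose_per_fraction <- function(n1, d1, n2 = 1, ratio) {
  check_ratio(ratio)
  if (any(n2 < 1)) stop("n2 must be >= 1", call. = FALSE)
  b <- bed(n1, d1, ratio)
  (ratio / 2) * (-1 + sqrt(1 + 4 * b / (n2 * ratio)))
}

#' Calculated/measured percentage
#'
#' The discrepancy statistic: the BED-calculated equivalent dose as a
#' percentage of the survival-curve-measured one, rounded half away from
#' zero to the nearest integer. Values below 100 mean the BED conversion
#' overestimates the effectiveness of the single hypofractionated dose.
#'
#' @param calculated Calculated equivalent dose, Gy (`>= 0`, vectorised).
#' @param measured Measured equivalent dose, Gy (`> 0`, vectorised).
#' @return Integer percentage(s).
#' @examples
#' cm_percent(5.96, 7.19) # 83
#' @export
cm_percent <- function(calculated, measured) {
  if (any(measured <= 0)) stop("`measured` must be > 0", call. = FALSE)
  if (any(calculated < 0)) stop("`calculated` must be >= 0", call. = FALSE)
  as.integer(round_half_away(100 * calculated / measured))
}

check_ratio <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio <= 0)) {
    stop("alpha/beta `ratio` must be > 0 and finite", call. = FALSE)
  }
  invisible(ratio)
}
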