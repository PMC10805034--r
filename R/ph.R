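#' Trapezoidal pH growth limitation
#'
#' Maps ambient pH to a growth-limitation factor in \[0, 1\] from four
#' ascending pH corners `c(c1, c2, c3, c4)`: the factor is 0 at or outside
#' `[c1, c4]`, 1 on the optimal plateau `[c2, c3]`, and piecewise-linear on
#' the shoulders. Vectorized over `ph`.
#'
#' @param ph pH value(s).
#' @param corners Four ascending pH values, `c1 < c2 <= c3 < c4`.
#' @param group Optional group name used in validation errors.
#' @return Numeric factor(s) in \[0, 1\].
#' @export
#' @examples
#' ph_limitation(5.5, c(5, 6, 7, 8)) # 0.5, halfway up the lower shoulder
ph_limitation <- function(ph, corners, group = "group") {
  validate_ph_corners(corners, group)
  lo <- (ph - corners[1]) / (corners[2] - corners[1])
  hi <- (corners[4] - ph) / (corners[4] - corners[3])
  pmax(0, pmin(1, lo, hi))
}
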