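#' Generalized equivalent uniform dose (gEUD)
#'
#' The uniform dose producing the same effect as the inhomogeneous
#' distribution: the generalized (power) mean of the bin representative
#' doses with organ-specific exponent `a`,
#' \deqn{EUD = \left(\sum_i v_i D_i^a\right)^{1/a}}
#' with \eqn{v_i} the fractional volume and \eqn{D_i} the midpoint dose of
#' bin \eqn{i}. `a = 1` recovers the mean dose; large `a` approaches the
#' maximum dose (serial organs); `a < 1` weights cold spots (parallel
#' organs). The gEUD is computed on physical bin dose, without
#' fractionation correction.
#'
#' @param d A [dvh()] with positive total volume.
#' @param a Nonzero exponent. All packaged organ exponents are positive;
#'   negative `a` (target-type EUD) is supported for completeness, in which
#'   case zero-dose bins are clamped to `zero_dose_floor`.
#' @param zero_dose_floor Dose floor (GyRBE) substituted for zero bin doses
#'   when `a < 0`; ignored for `a > 0` (zero-dose bins then contribute 0).
#' @return EUD in GyRBE, bounded by the min and max bin representative dose.
#' @examples
#' d <- dvh("x", c(0, 10, 20), c(50, 50))
#' geud(d, a = 2)
#' all.equal(geud(d, 1), mean_dose(d))
#' @export
geud <- function(d, a, zero_dose_floor = 1e-3) {
  stopifnot(is_dvh(d), length(a) == 1L, is.finite(a))
  if (a == 0) stop("gEUD exponent a must be nonzero")
  v <- bin_fractions(d)
  D <- bin_midpoints(d)
  keep <- v > 0
  v <- v[keep]; D <- D[keep]
  if (a < 0) D <- pmax(D, zero_dose_floor)
  # scale by the max dose for numerical stability at large |a|
  s <- max(D)
  if (s == 0) return(0)
  s * sum(v * (D / s)^a)^(1 / a)
}
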