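#' Dose-volume histogram (differential form)
#'
#' Construct a validated differential DVH: dose bins defined by strictly
#' increasing edges starting at 0 GyRBE, with an absolute volume (cc) per bin.
#' The differential representation is canonical; the cumulative form is
#' derived on demand with [to_cumulative()].
#'
#' @param structure Structure name (single string), e.g. `"liver"` or `"body"`.
#' @param edges Numeric vector of bin edges in GyRBE, strictly increasing,
#'   first edge 0; length is one more than `bin_volume`.
#' @param bin_volume Numeric vector of per-bin volumes in cc, all `>= 0`.
#' @return An object of class `"dvh"`: a list with fields `structure`,
#'   `edges`, `bin_volume` and `total_volume` (cc, the sum of `bin_volume`).
#' @examples
#' d <- dvh("organ", edges = c(0, 10, 20, 30), bin_volume = c(10, 20, 30))
#' d$total_volume  # 60
#' mean_dose(d)
#' @export
dvh <- function(structure, edges, bin_volume) {
  stopifnot(is.character(structure), length(structure) == 1L)
  edges <- as.numeric(edges)
  bin_volume <- as.numeric(bin_volume)
  if (length(edges) != length(bin_volume) + 1L)
    stop("`edges` must have exactly one more element than `bin_volume`")
  if (length(bin_volume) < 1L)
    stop("empty DVH: at least one bin is required")
  if (any(!is.finite(edges)) || any(!is.finite(bin_volume)))
    stop("DVH edges and volumes must be finite")
  if (any(diff(edges) <= 0))
    stop("DVH bin edges must be strictly increasing")
  if (abs(edges[1L]) > .Machine$double.eps)
    stop("first DVH bin edge must be 0")
  if (any(bin_volume < 0))
    stop(sprintf("negative bin volume in structure '%s'", structure))
  structure(
    list(structure = structure, edges = edges, bin_volume = bin_volume,
         total_volume = sum(bin_volume)),
    class = "dvh"
  )
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> %s: %d bins over [0, %.4g] GyRBE, %.4g cc, mean %.4g GyRBE\n",
              x$structure, length(x$bin_volume), max(x$edges), x$total_volume,
              if (x$total_volume > 0) mean_dose(x) else NA_real_))
  invisible(x)
}

#' Test for a DVH object
#' @param x Any object.
#' @return `TRUE` if `x` is a [dvh()].
#' @export
is_dvh <- function(x) inherits(x, "dvh")

# representative dose per bin: midpoint of [edge_i, edge_{i+1})
bin_midpoints <- function(d) (d$edges[-length(d$edges)] + d$edges[-1L]) / 2

# fractional volume per bin
bin_fractions <- function(d) {
  if (d$total_volume <= 0) stop("DVH has zero total volume")
  d$bin_volume / d$total_volume
}

#' Build a DVH from a cumulative representation
#'
#' A cumulative DVH row gives the volume receiving at least the row's dose,
#' sampled at the bin left edges (first dose must be 0, where the volume equals
#' the total structure volume). If the last cumulative volume is nonzero, a
#' final bin is appended whose width equals the preceding edge spacing, so
#' that [to_cumulative()] followed by `dvh_from_cumulative()` is an exact
#' round trip.
#'
#' @param structure Structure name.
#' @param dose Strictly increasing dose values (GyRBE), first value 0.
#' @param volume Non-increasing cumulative volumes (cc); `volume[1]` is the
#'   total structure volume.
#' @return A [dvh()] in canonical differential form.
#' @export
dvh_from_cumulative <- function(structure, dose, volume) {
  dose <- as.numeric(dose); volume <- as.numeric(volume)
  if (length(dose) != length(volume) || length(dose) < 2L)
    stop("cumulative DVH needs matching dose/volume vectors of length >= 2")
  if (any(diff(volume) > 1e-9 * max(abs(volume), 1)))
    stop(sprintf("cumulative volumes must be non-increasing (structure '%s')",
                 structure))
  volume <- cummin(pmax(volume, 0))  # absorb sub-tolerance ripple
  if (volume[length(volume)] > 0) {
    # open final bin: close it with the last edge spacing
    w <- dose[length(dose)] - dose[length(dose) - 1L]
    dose <- c(dose, dose[length(dose)] + w)
    volume <- c(volume, 0)
  }
  dvh(structure, edges = dose, bin_volume = -diff(volume))
}

#' Cumulative representation of a DVH
#'
#' @param d A [dvh()].
#' @return A data frame with columns `dose` (bin left edges, GyRBE) and
#'   `volume_cc` (volume receiving at least that dose). The first row is
#'   (0, total_volume); volumes are non-increasing.
#' @export
to_cumulative <- function(d) {
  stopifnot(is_dvh(d))
  data.frame(
    dose = d$edges[-length(d$edges)],
    volume_cc = rev(cumsum(rev(d$bin_volume)))
  )
}

#' Volume-weighted mean dose of a DVH
#'
#' @param d A [dvh()] with positive total volume.
#' @return Mean dose in GyRBE, using bin-midpoint representative doses.
#' @export
mean_dose <- function(d) {
  stopifnot(is_dvh(d))
  sum(bin_fractions(d) * bin_midpoints(d))
}

#' Volume receiving at least a threshold dose (Vx)
#'
#' Linear interpolation of the cumulative DVH inside the containing bin;
#' beyond the maximum dose edge the volume is 0.
#'
#' @param d A [dvh()].
#' @param threshold Dose threshold in GyRBE, `>= 0`.
#' @param unit `"cc"` (absolute) or `"percent"` (relative to total volume).
#' @return Volume at or above `threshold`, in the requested unit.
#' @export
volume_at_dose <- function(d, threshold, unit = c("cc", "percent")) {
  stopifnot(is_dvh(d))
  unit <- match.arg(unit)
  if (any(threshold < 0)) stop("dose threshold must be >= 0")
  cum <- to_cumulative(d)
  x <- c(cum$dose, d$edges[length(d$edges)])
  y <- c(cum$volume_cc, 0)
  v <- stats::approx(x, y, xout = threshold, rule = 2)$y
  if (unit == "percent") v <- 100 * v / d$total_volume
  v
}

#' Minimum dose to the hottest given volume (Dx)
#'
#' Inverse of [volume_at_dose()] under the same linear-interpolation
#' convention; across flat (zero-volume) segments the smallest such dose is
#' returned.
#'
#' @param d A [dvh()].
#' @param volume Volume in the requested unit, in `(0, total_volume]`
#'   (or `(0, 100]` for percent).
#' @param unit `"cc"` or `"percent"`.
#' @return Dose in GyRBE.
#' @export
dose_at_volume <- function(d, volume, unit = c("cc", "percent")) {
  stopifnot(is_dvh(d), length(volume) == 1L)
  unit <- match.arg(unit)
  if (unit == "percent") volume <- volume / 100 * d$total_volume
  if (volume <= 0 || volume > d$total_volume * (1 + 1e-12))
    stop("requested volume is outside (0, total_volume]")
  cum <- to_cumulative(d)
  x <- c(cum$dose, d$edges[length(d$edges)])
  y <- c(cum$volume_cc, 0)
  # first index where the cumulative curve drops to or below `volume`
  k <- which(y <= volume + 1e-12)[1L]
  if (k == 1L) return(x[1L])
  if (abs(y[k] - volume) <= 1e-12) return(x[k])
  # interpolate inside bin (k-1, k): y[k-1] > volume > y[k]
  x[k - 1L] + (y[k - 1L] - volume) * (x[k] - x[k - 1L]) / (y[k - 1L] - y[k])
}
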