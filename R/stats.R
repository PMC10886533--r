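#' Paired Wilcoxon signed-rank test (two-sided)
#'
#' Convention-enforcing wrapper: zero differences are dropped (signed-rank
#' convention, not Pratt); the p-value is exact by enumeration of sign
#' assignments when the nonzero differences are untied and few, otherwise a
#' normal approximation with tie and continuity correction is used. If all
#' differences are zero, `p = 1` with a warning.
#'
#' @param values_a,values_b Equal-length numeric vectors of paired
#'   per-patient values (modality A vs B), length `>= 2`.
#' @param exact Passed to [stats::wilcox.test()]; `NULL` (default) selects
#'   the exact test whenever it is available.
#' @return Two-sided p-value in `(0, 1]`.
#' @export
wilcoxon_signed_rank <- function(values_a, values_b, exact = NULL) {
  if (length(values_a) != length(values_b))
    stop("paired samples must have equal length")
  if (length(values_a) < 2L) stop("paired test requires n >= 2")
  d <- values_a - values_b
  d <- d[d != 0]
  if (!length(d)) {
    warning("all paired differences are zero; p = 1")
    return(1)
  }
  suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = TRUE)$p.value
  )
}

#' Mean with t-based 95% confidence interval
#'
#' `mean +/- t(1 - (1-conf)/2, n-1) * s / sqrt(n)`.
#'
#' @param values Numeric vector, length `>= 2`.
#' @param conf Confidence level (default 0.95).
#' @return A list with `mean`, `lower`, `upper`, `half_width`, `n`.
#' @export
mean_ci <- function(values, conf = 0.95) {
  n <- length(values)
  if (n < 2L) stop("confidence interval requires n >= 2")
  m <- mean(values)
  hw <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * stats::sd(values) / sqrt(n)
  list(mean = m, lower = m - hw, upper = m + hw, half_width = hw, n = n)
}

#' Conformality ratio of a threshold volume between two modalities
#'
#' Per patient, the ratio of the volume receiving at least `threshold` GyRBE
#' (default V20 of the body, the prescription-isodose conformality metric)
#' between two modalities, then the cohort mean with its t-based CI.
#' Patients with a zero denominator volume are excluded with a warning.
#'
#' @param cohort List of [patient_record()] objects; both modalities must be
#'   present for every patient.
#' @param pair Character vector `c(numerator, denominator)` of modalities,
#'   default `c("VMAT", "3D")`.
#' @param threshold Dose threshold in GyRBE (default 20).
#' @param structure Structure evaluated (default `"body"`).
#' @return A list as from [mean_ci()], plus `ratios` (per patient).
#' @export
conformality_ratio <- function(cohort, pair = c("VMAT", "3D"), threshold = 20,
                               structure = "body") {
  stopifnot(length(pair) == 2L)
  ratios <- vapply(cohort, function(pt) {
    va <- volume_at_dose(pt$plans[[pair[1L]]]$dvhs[[structure]], threshold)
    vb <- volume_at_dose(pt$plans[[pair[2L]]]$dvhs[[structure]], threshold)
    if (vb == 0) return(NA_real_)
    va / vb
  }, numeric(1))
  if (anyNA(ratios)) {
    warning(sprintf("%d patient(s) excluded: zero %s V%g in %s",
                    sum(is.na(ratios)), structure, threshold, pair[2L]))
    ratios <- ratios[!is.na(ratios)]
  }
  out <- mean_ci(ratios)
  out$ratios <- ratios
  out
}

#' Percent reduction between two totals
#'
#' `100 * (1 - total_b / total_a)`; negative when `total_b` exceeds
#' `total_a` (an increase). Reported reductions are conventionally rounded
#' to the nearest integer percent after applying [report_round()] to the
#' totals.
#'
#' @param total_a Reference total, `> 0`.
#' @param total_b Comparison total.
#' @return Percent reduction (unrounded).
#' @export
percent_reduction <- function(total_a, total_b) {
  if (any(total_a <= 0)) stop("reference total must be > 0")
  100 * (1 - total_b / total_a)
}
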