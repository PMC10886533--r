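#' Risk-equivalent dose (RED) dose-response models
#'
#' Per-dose-point response entering the organ equivalent dose, under the
#' mechanistic carcinoma-induction framework with linear-quadratic
#' fractionation correction. With
#' \eqn{\alpha' = \alpha (1 + d / (\alpha/\beta))}, where `d` is the dose
#' per fraction:
#' \itemize{
#'   \item linear: \eqn{RED = D}
#'   \item bell (full cell kill, no repopulation): \eqn{RED = D e^{-\alpha' D}}
#'   \item plateau (full repopulation): \eqn{RED = (1 - e^{-\alpha' D})/\alpha'}
#'   \item mechanistic (repopulation/repair parameter \eqn{R \in (0,1)}):
#'     \deqn{RED = \frac{e^{-\alpha' D}}{\alpha' R}\left[1 - 2R + R^2 e^{\alpha' D}
#'       - (1-R)^2 e^{-\frac{\alpha' R D}{1-R}}\right]}
#' }
#' The mechanistic form converges to the bell model as \eqn{R \to 0} and to
#' the plateau model as \eqn{R \to 1}; `R` exactly at an endpoint is
#' dispatched to the corresponding closed form rather than evaluated.
#'
#' @param dose Dose D in GyRBE (vectorized), `>= 0`.
#' @param dose_per_fraction Dose per fraction d in GyRBE (scalar or same
#'   length as `dose`).
#' @param params One row of a risk registry (see [default_risk_params()]),
#'   or any list with `model`, `alpha`, `R`, `alpha_beta`.
#' @return RED in GyRBE, same length as `dose`; `RED(0) = 0` for every
#'   model.
#' @export
red <- function(dose, dose_per_fraction, params) {
  if (any(dose < 0)) stop("dose must be >= 0")
  if (any(dose_per_fraction < 0)) stop("dose per fraction must be >= 0")
  model <- params$model
  alpha <- params$alpha
  ab <- params$alpha_beta %||% 3
  if (model == "linear") return(dose + 0 * dose_per_fraction)
  ap <- alpha * (1 + dose_per_fraction / ab)  # alpha-prime, per Gy
  eps <- 1e-12
  if (model == "mechanistic") {
    R <- params$R
    if (R <= eps) model <- "bell" else if (R >= 1 - eps) model <- "plateau"
  }
  out <- switch(model,
    bell = dose * exp(-ap * dose),
    plateau = ifelse(ap * dose < eps, dose, -expm1(-ap * dose) / ap),
    mechanistic = {
      R <- params$R
      bracket <- 1 - 2 * R + R^2 * exp(ap * dose) -
        (1 - R)^2 * exp(-ap * R * dose / (1 - R))
      ifelse(ap * dose < eps, dose, exp(-ap * dose) / (ap * R) * bracket)
    },
    stop(sprintf("unknown RED model '%s'", model))
  )
  pmax(out, 0)  # guard against sign noise from cancellation near R endpoints
}

#' Organ equivalent dose (OED)
#'
#' Dose-response-weighted average of the DVH: the uniform dose carrying the
#' same secondary-cancer induction as the inhomogeneous distribution,
#' \deqn{OED = \sum_i v_i \, RED(D_i, d_i)}
#' with \eqn{d_i = D_i / n_{fractions}} (each dose level is taken as
#' delivered over the plan's full fraction count). For the linear model the
#' OED equals the mean dose exactly.
#'
#' @param d A [dvh()].
#' @param params Organ risk parameters (one registry row).
#' @param n_fractions Fraction count of the plan delivering `d`.
#' @return OED in GyRBE.
#' @export
oed <- function(d, params, n_fractions) {
  stopifnot(is_dvh(d), n_fractions >= 1)
  v <- bin_fractions(d)
  D <- bin_midpoints(d)
  sum(v * red(D, D / n_fractions, params))
}

#' Excess absolute risk (EAR) at an attained age
#'
#' \deqn{EAR(age_x, age_a) = \beta_{EAR} \cdot OED \cdot
#'   e^{\gamma_e (age_x - 30)} (age_a / 70)^{\gamma_a}}
#' in excess cases per 10,000 person-years. The age modifier is 1 at
#' exposure age 30 and attained age 70.
#'
#' @param oed_value OED in GyRBE, `>= 0`.
#' @param params Organ risk parameters (`beta_ear`, `gamma_e`, `gamma_a`).
#' @param age_exposure Age at treatment, years.
#' @param age_attained Attained age, years (vectorized), `>= age_exposure`.
#' @return EAR per 10,000 person-years.
#' @export
ear <- function(oed_value, params, age_exposure, age_attained) {
  stopifnot(oed_value >= 0)
  if (any(age_attained < age_exposure))
    stop("attained age must be >= age at exposure")
  mu <- exp(params$gamma_e * (age_exposure - 30) +
              params$gamma_a * log(age_attained / 70))
  params$beta_ear * oed_value * mu
}

#' Lifetime attributable risk (LAR) projected to a horizon age
#'
#' Discrete yearly accumulation of the EAR from the end of the latency
#' period to the projection age (inclusive), converted from excess cases
#' per 10,000 person-years to percent lifetime risk:
#' \deqn{LAR = 100 \sum_{a = age_x + latency}^{70} EAR(age_x, a) / 10{,}000}
#' No competing-mortality survival weighting is applied.
#'
#' @param oed_value OED in GyRBE.
#' @param params Organ risk parameters.
#' @param age_exposure Age at treatment, years.
#' @param projection_age Horizon age (default 70).
#' @param latency Risk-free latency after exposure in years (default 5).
#' @return LAR in percent; 0 (with a warning) if the projection window is
#'   empty.
#' @export
lar <- function(oed_value, params, age_exposure, projection_age = 70,
                latency = 5) {
  stopifnot(latency >= 0)
  if (age_exposure >= projection_age)
    stop("age at exposure must be below the projection age")
  start <- age_exposure + latency
  if (start > projection_age) {
    warning("projection window is empty; LAR = 0")
    return(0)
  }
  ages <- seq(start, projection_age, by = 1)
  100 * sum(ear(oed_value, params, age_exposure, ages)) / 1e4
}

#' Window-averaged EAR (headline cohort value)
#'
#' A single reported EAR per organ: the mean of the yearly EAR over the
#' same attained-age window used by [lar()] (latency end through the
#' projection age). Per-age values are available via [ear()].
#'
#' @inheritParams lar
#' @return EAR per 10,000 person-years averaged over the projection window.
#' @export
ear_window_mean <- function(oed_value, params, age_exposure,
                            projection_age = 70, latency = 5) {
  start <- age_exposure + latency
  if (start > projection_age) return(0)
  ages <- seq(start, projection_age, by = 1)
  mean(ear(oed_value, params, age_exposure, ages))
}

#' Total risk across organs
#'
#' Arithmetic sums of per-organ EAR and LAR values as given (no re-rounding
#' before summation).
#'
#' @param results Data frame with columns `organ`, `ear`, `lar`, one row per
#'   organ; duplicate organs are an error.
#' @return Named numeric vector `c(ear = , lar = )`; `c(0, 0)` for an empty
#'   input.
#' @export
total_risk <- function(results) {
  if (is.null(results) || nrow(results) == 0) return(c(ear = 0, lar = 0))
  stopifnot(all(c("organ", "ear", "lar") %in% names(results)))
  dup <- unique(results$organ[duplicated(results$organ)])
  if (length(dup))
    stop(sprintf("duplicate organ(s) in risk results: %s",
                 paste(dup, collapse = ", ")))
  c(ear = sum(results$ear), lar = sum(results$lar))
}
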