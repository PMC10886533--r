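#' Synthetic-cohort geometry and calibration defaults
#'
#' Loads the frozen generator calibration: per-modality mixture profiles,
#' the body-structure profiles solved against the published cohort anchors
#' (body mean dose and V20 conformality ratios), and per-organ volumes and
#' target mean doses. See the methods vignette for the derivation.
#'
#' @param path Optional YAML override.
#' @return Nested list with elements `modality_profiles`, `body`, `organs`.
#' @export
organ_geometry <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "organ_geometry.yaml", package = "dvhrisk",
                        mustWork = TRUE)
  yaml::read_yaml(path)
}

modalities <- function() c("3D", "VMAT", "PBS")

# run fn() under a temporary RNG state seeded with `seed`
local_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# unit-mass discretized mixture components on the shared dose grid
component_masses <- function(edges, prescription, sigma_rx, bath_scale) {
  lo <- edges[-length(edges)]
  hi <- edges[-1L]
  cap <- edges[length(edges)]
  z <- stats::pnorm(cap, prescription, sigma_rx) -
    stats::pnorm(0, prescription, sigma_rx)
  rx <- (stats::pnorm(hi, prescription, sigma_rx) -
           stats::pnorm(lo, prescription, sigma_rx)) / z
  zb <- stats::pexp(cap, 1 / bath_scale)
  bath <- (stats::pexp(hi, 1 / bath_scale) - stats::pexp(lo, 1 / bath_scale)) / zb
  list(rx = rx, bath = bath)
}

# assemble a differential DVH from mixture fractions (remainder at zero dose)
simulate_organ_dvh <- function(structure, volume_cc, f_rx, f_bath, edges,
                               comp) {
  if (f_rx + f_bath > 1) {  # keep the zero-dose remainder non-negative
    sc <- 1 / (f_rx + f_bath)
    f_rx <- f_rx * sc
    f_bath <- f_bath * sc
  }
  mass <- f_rx * comp$rx + f_bath * comp$bath
  mass[1L] <- mass[1L] + max(0, 1 - f_rx - f_bath)
  dvh(structure, edges, mass * volume_cc)
}

# solve base mixture fractions so the discretized mean hits the target
solve_fractions <- function(target_mean, profile, comp, mids) {
  rx_mean <- sum(comp$rx * mids)
  bath_mean <- sum(comp$bath * mids)
  f_bath <- min(profile$bath_cap, (1 - profile$phi) * target_mean / profile$bath_scale)
  f_rx <- max(0, (target_mean - f_bath * bath_mean) / rx_mean)
  c(f_rx = f_rx, f_bath = f_bath)
}

#' Generate one synthetic patient (three plans)
#'
#' Builds one [patient_record()] with a 3D, VMAT and PBS plan sharing the
#' same 14 structures (13 organs plus body). Each structure's differential
#' DVH is a mixture of a near-prescription normal component
#' (`f_rx * N(D_p, sigma_rx)`), an exponential low-dose bath
#' (`f_bath * Exp(bath_scale)`), and the remaining volume at zero dose,
#' truncated to `[0, 1.1 * D_p]` (clinically acceptable hotspot cap) and
#' discretized at `bin_width`. Base fractions come from the frozen
#' calibration in [organ_geometry()]; per-patient anatomical variability is
#' a lognormal multiplier (mean 1, log-sd `sigma_log`) on `f_rx` and
#' `f_bath`, shared across modalities so that paired comparisons remain
#' paired, plus a small independent per-modality lognormal jitter
#' (`sigma_modality`). Deterministic for a fixed seed; the caller's RNG
#' state is left untouched.
#'
#' @param seed Integer seed for this patient.
#' @param stage `"IIA"` (30 GyRBE in 15 fractions) or `"IIB"` (36 GyRBE in
#'   18 fractions).
#' @param age Age at treatment in years.
#' @param patient_id Patient label.
#' @param geometry Calibration list from [organ_geometry()].
#' @param sigma_log Log-sd of the shared per-patient multiplier
#'   (default 0.25).
#' @param sigma_modality Log-sd of the per-modality jitter (default 0.05).
#' @param sigma_volume Log-sd of the per-patient structure-volume
#'   multiplier (default 0.15).
#' @param sigma_rx Spread (GyRBE) of the near-prescription component
#'   (default 1.5).
#' @param bin_width Dose bin width in GyRBE (default 0.1).
#' @return A [patient_record()].
#' @export
generate_patient <- function(seed, stage = c("IIA", "IIB"), age,
                             patient_id = sprintf("P%06d", seed %% 1000000L),
                             geometry = organ_geometry(),
                             sigma_log = 0.25, sigma_modality = 0.05,
                             sigma_volume = 0.15, sigma_rx = 1.5,
                             bin_width = 0.1) {
  stage <- match.arg(stage)
  dp <- if (stage == "IIA") 30 else 36
  nfx <- if (stage == "IIA") 15L else 18L
  edges <- seq(0, round(1.1 * dp / bin_width) * bin_width, by = bin_width)
  mids <- (edges[-length(edges)] + edges[-1L]) / 2
  mods <- modalities()

  # per-modality unit components on the shared grid
  prof <- geometry$modality_profiles
  comp_organ <- lapply(mods, function(m)
    component_masses(edges, dp, sigma_rx, prof[[m]]$bath_scale))
  names(comp_organ) <- mods
  comp_body <- lapply(mods, function(m)
    component_masses(edges, dp, sigma_rx, geometry$body$profiles[[m]]$bath_scale))
  names(comp_body) <- mods

  local_seed(seed, function() {
    dvhs <- stats::setNames(vector("list", length(mods)), mods)
    for (m in mods) dvhs[[m]] <- list()
    build <- function(structure, volume_cc, base) {
      vol <- volume_cc * stats::rlnorm(1, -sigma_volume^2 / 2, sigma_volume)
      m_rx <- stats::rlnorm(1, -sigma_log^2 / 2, sigma_log)
      m_bath <- stats::rlnorm(1, -sigma_log^2 / 2, sigma_log)
      for (m in mods) {
        j <- stats::rlnorm(2, -sigma_modality^2 / 2, sigma_modality)
        comp <- if (structure == "body") comp_body[[m]] else comp_organ[[m]]
        dvhs[[m]][[structure]] <<- simulate_organ_dvh(
          structure, vol,
          f_rx = base[[m]]["f_rx"] * m_rx * j[1L],
          f_bath = base[[m]]["f_bath"] * m_bath * j[2L],
          edges = edges, comp = comp)
      }
    }
    body_base <- lapply(mods, function(m) {
      p <- geometry$body$profiles[[m]]
      c(f_rx = p$f_rx, f_bath = p$f_bath)
    })
    names(body_base) <- mods
    build("body", geometry$body$volume_cc, body_base)
    for (org in names(geometry$organs)) {
      g <- geometry$organs[[org]]
      base <- lapply(mods, function(m)
        solve_fractions(g$target_mean[[m]], prof[[m]], comp_organ[[m]], mids))
      names(base) <- mods
      build(org, g$volume_cc, base)
    }
    plans <- lapply(mods, function(m)
      plan_record(patient_id, m, dp, nfx, dvhs[[m]]))
    names(plans) <- mods
    patient_record(patient_id, age, stage, plans)
  })
}

#' Generate a synthetic cohort
#'
#' Default conditions emulate the published 10-patient stage II seminoma
#' planning cohort: stages alternate IIA/IIB (so `n = 10` yields five of
#' each), ages are drawn uniformly from the integers 32-54. Per-patient
#' child seeds are derived from the master seed by a counter
#' (`child = (seed mod 2e6) * 1000 + i`), so extending the cohort does not
#' reshuffle existing patients.
#'
#' @param n Number of patients (default 10).
#' @param seed Master seed (default 1).
#' @param ... Passed to [generate_patient()].
#' @return List of [patient_record()] objects.
#' @export
generate_cohort <- function(n = 10, seed = 1, ...) {
  stopifnot(n >= 1)
  stages <- rep(c("IIA", "IIB"), length.out = n)
  ages <- local_seed(seed, function() sample(32:54, n, replace = TRUE))
  child <- (abs(as.integer(seed)) %% 2000000L) * 1000L + seq_len(n)
  lapply(seq_len(n), function(i)
    generate_patient(seed = child[i], stage = stages[i], age = ages[i],
                     patient_id = sprintf("P%02d", i), ...))
}
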