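#' Per-patient dosimetry table
#'
#' For every patient, modality and structure: structure volume, mean dose,
#' gEUD (for the 13 organs with a packaged exponent; `NA` for body), body
#' V20 and pelvic-ilium V10 in cc (reported on their own structures' rows).
#'
#' @param cohort List of [patient_record()] objects.
#' @param eud_table gEUD exponent registry from [default_eud_params()].
#' @return A tibble with one row per patient x modality x structure and
#'   columns `patient_id`, `stage`, `age`, `modality`, `structure`,
#'   `volume_cc`, `mean_dose`, `eud`, `v20_cc`, `v10_cc`.
#' @export
run_dosimetry <- function(cohort, eud_table = default_eud_params()) {
  a_of <- stats::setNames(eud_table$a, eud_table$organ)
  rows <- list()
  for (pt in cohort) {
    for (m in names(pt$plans)) {
      pl <- pt$plans[[m]]
      missing <- setdiff(eud_table$organ, names(pl$dvhs))
      if (length(missing))
        stop(sprintf("patient '%s' (%s): missing structure(s) %s",
                     pt$patient_id, m, paste(missing, collapse = ", ")))
      for (s in names(pl$dvhs)) {
        d <- pl$dvhs[[s]]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          patient_id = pt$patient_id, stage = pt$stage,
          age = pt$age_at_treatment, modality = m, structure = s,
          volume_cc = d$total_volume,
          mean_dose = mean_dose(d),
          eud = if (s %in% names(a_of)) geud(d, a_of[[s]]) else NA_real_,
          v20_cc = volume_at_dose(d, 20),
          v10_cc = volume_at_dose(d, 10))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Per-patient secondary-cancer risk table
#'
#' For every patient, modality and risk-modelled organ: OED under the
#' organ's dose-response model, the window-averaged EAR, and the LAR
#' projected to `projection_age`. Organs present in the plans but absent
#' from the risk registry (the bone structures here) are skipped with a
#' warning listing them.
#'
#' @param cohort List of [patient_record()] objects.
#' @param params Risk registry from [default_risk_params()].
#' @param projection_age Horizon age (default 70).
#' @param latency Latency in years (default 5).
#' @return A tibble with columns `patient_id`, `stage`, `age`, `modality`,
#'   `organ`, `oed`, `ear`, `lar`.
#' @export
run_risk <- function(cohort, params = default_risk_params(),
                     projection_age = 70, latency = 5) {
  rows <- list()
  skipped <- character()
  for (pt in cohort) {
    for (m in names(pt$plans)) {
      pl <- pt$plans[[m]]
      organs <- setdiff(names(pl$dvhs), "body")
      for (s in organs) {
        pr <- params[params$organ == s, ]
        if (nrow(pr) == 0L) {
          skipped <- union(skipped, s)
          next
        }
        o <- oed(pl$dvhs[[s]], pr, pl$n_fractions)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          patient_id = pt$patient_id, stage = pt$stage,
          age = pt$age_at_treatment, modality = m, organ = s, oed = o,
          ear = ear_window_mean(o, pr, pt$age_at_treatment, projection_age,
                                latency),
          lar = lar(o, pr, pt$age_at_treatment, projection_age, latency))
      }
    }
  }
  if (length(skipped))
    warning(sprintf("no risk parameters for: %s (dosimetry only)",
                    paste(sort(skipped), collapse = ", ")))
  dplyr::bind_rows(rows)
}

# cohort mean + CI + pairwise Wilcoxon flags for one metric column
summarize_metric <- function(df, key, value) {
  wide <- tidyr::pivot_wider(df[, c("patient_id", key, "modality", value)],
                             names_from = "modality",
                             values_from = dplyr::all_of(value))
  grp <- dplyr::group_by(df, dplyr::across(dplyr::all_of(c(key, "modality"))))
  single <- length(unique(df$patient_id)) < 2L
  summ <- dplyr::summarise(
    grp,
    mean = mean(.data[[value]]),
    ci_lower = if (single) NA_real_ else mean_ci(.data[[value]])$lower,
    ci_upper = if (single) NA_real_ else mean_ci(.data[[value]])$upper,
    .groups = "drop")
  pair_p <- function(sub, a, b) {
    if (!all(c(a, b) %in% names(sub)) || nrow(sub) < 2L) return(NA_real_)
    wilcoxon_signed_rank(sub[[a]], sub[[b]])
  }
  pvals <- dplyr::summarise(
    dplyr::group_by(wide, dplyr::across(dplyr::all_of(key))),
    p_3d_vmat = pair_p(dplyr::pick(dplyr::everything()), "3D", "VMAT"),
    p_vmat_pbs = pair_p(dplyr::pick(dplyr::everything()), "VMAT", "PBS"),
    p_3d_pbs = pair_p(dplyr::pick(dplyr::everything()), "3D", "PBS"),
    .groups = "drop")
  dplyr::left_join(summ, pvals, by = key)
}

#' Cohort dosimetry summary (per-organ means, CIs, paired tests)
#'
#' Cohort means with 95% t-based CIs of the gEUD and mean dose for each of
#' the 13 organs and modality, with two-sided paired Wilcoxon p-values and
#' significance flags at 0.05 for 3D-vs-VMAT (`*`), VMAT-vs-PBS
#' (`†`) and 3D-vs-PBS. For a single-patient cohort the means equal
#' the patient's values and CIs and p-values are suppressed (`NA`).
#'
#' @param dosimetry Output of [run_dosimetry()].
#' @return Named list of tibbles `eud` and `mean_dose`.
#' @export
summarize_dosimetry <- function(dosimetry) {
  check_complete(dosimetry, "structure")
  org <- dosimetry[!is.na(dosimetry$eud), ]
  list(eud = flag_significance(summarize_metric(org, "structure", "eud")),
       mean_dose = flag_significance(summarize_metric(org, "structure", "mean_dose")))
}

flag_significance <- function(tb) {
  tb$sig_3d_vmat <- ifelse(!is.na(tb$p_3d_vmat) & tb$p_3d_vmat < 0.05, "*", "")
  tb$sig_vmat_pbs <- ifelse(!is.na(tb$p_vmat_pbs) & tb$p_vmat_pbs < 0.05, "\u2020", "")
  tb
}

check_complete <- function(df, key) {
  grid <- expand.grid(patient_id = unique(df$patient_id),
                      modality = unique(df$modality),
                      key = unique(df[[key]]), stringsAsFactors = FALSE)
  have <- paste(df$patient_id, df$modality, df[[key]])
  want <- paste(grid$patient_id, grid$modality, grid$key)
  miss <- setdiff(want, have)
  if (length(miss))
    stop(sprintf("incomplete results; missing cells: %s",
                 paste(miss, collapse = "; ")))
  invisible(df)
}

#' Cohort risk summary with totals and percent reductions
#'
#' Per-organ cohort means with CIs and paired-test flags for OED, EAR and
#' LAR; per-modality totals (per-patient organ sums, then the cohort mean);
#' and percent reductions of the total EAR/LAR of VMAT and PBS relative to
#' 3D. Reductions are computed from reporting-rounded totals
#' ([report_round()]) and rounded to integer percent, mirroring the
#' published arithmetic.
#'
#' @param risk Output of [run_risk()] (or any table with `patient_id`,
#'   `modality`, `organ`, `ear`, `lar`, optionally `oed`).
#' @param baseline If `TRUE`, append the general-population baseline
#'   incidence column to the per-organ EAR table.
#' @return Named list: `per_organ` (tibbles `ear`, `lar`, and `oed` when
#'   present), `totals` (modality, mean total EAR and LAR), `reductions`
#'   (comparison, metric, percent).
#' @export
summarize_risk <- function(risk, baseline = FALSE) {
  check_complete(risk, "organ")
  metrics <- intersect(c("oed", "ear", "lar"), names(risk))
  per_organ <- lapply(metrics, function(v)
    flag_significance(summarize_metric(risk, "organ", v)))
  names(per_organ) <- metrics
  if (baseline)
    per_organ$ear <- dplyr::left_join(per_organ$ear, baseline_incidence(),
                                      by = "organ")
  pt_tot <- dplyr::summarise(
    dplyr::group_by(risk, .data$patient_id, .data$modality),
    ear = total_risk(dplyr::pick(dplyr::all_of(c("organ", "ear", "lar"))))[["ear"]],
    lar = total_risk(dplyr::pick(dplyr::all_of(c("organ", "ear", "lar"))))[["lar"]],
    .groups = "drop")
  totals <- dplyr::summarise(dplyr::group_by(pt_tot, .data$modality),
                             total_ear = mean(.data$ear),
                             total_lar = mean(.data$lar), .groups = "drop")
  tot_of <- function(mod, col) totals[totals$modality == mod, ][[col]]
  reductions <- NULL
  if (all(c("3D", "VMAT", "PBS") %in% totals$modality)) {
    redn <- function(mod, col) round(percent_reduction(
      report_round(tot_of("3D", col)), report_round(tot_of(mod, col))))
    reductions <- tibble::tibble(
      comparison = rep(c("VMAT vs 3D", "PBS vs 3D"), each = 2),
      metric = rep(c("EAR", "LAR"), 2),
      percent = c(redn("VMAT", "total_ear"), redn("VMAT", "total_lar"),
                  redn("PBS", "total_ear"), redn("PBS", "total_lar")))
  }
  list(per_organ = per_organ, totals = totals, reductions = reductions)
}
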