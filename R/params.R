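#' Packaged gEUD exponents
#'
#' Organ-specific volume-effect exponents `a` for the generalized equivalent
#' uniform dose, for the 13 organs at risk contoured in the stage II seminoma
#' cohort (serial structures such as the spinal cord carry large `a`,
#' parallel structures such as the liver carry `a` near or below 1).
#'
#' @param path Optional path to a YAML file overriding the packaged registry;
#'   the file maps organ name to `a`.
#' @return A tibble with columns `organ` and `a`.
#' @export
default_eud_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "eud_a_values.yaml", package = "dvhrisk",
                        mustWork = TRUE)
  y <- yaml::read_yaml(path)
  tb <- tibble::tibble(organ = canonical_structure(names(y)),
                       a = vapply(y, as.numeric, numeric(1)))
  if (any(tb$a == 0)) stop("gEUD exponent a must be nonzero")
  tb
}

#' Load an organ risk-parameter registry
#'
#' Reads a YAML registry with one block per organ giving the dose-response
#' `model` (`linear`, `bell`, `plateau`, or `mechanistic`), the
#' linear-quadratic cell-kill parameter `alpha` (1/Gy), the
#' repopulation/repair parameter `R` in `[0, 1]`, the initial risk slope
#' `beta_ear` (excess cases per 10,000 person-years per Gy), the
#' age-modifier exponents `gamma_e` (per year of age at exposure, centred at
#' 30) and `gamma_a` (power of attained age over 70), and the fractionation
#' ratio `alpha_beta` (Gy; 3 for all normal organs here). Kidneys and
#' pancreas entries, when absent, are cloned from the small-bowel block at
#' load time (their carcinoma-induction coefficients are taken to match the
#' small bowel).
#'
#' The packaged default is a clearly labelled *demonstration* registry (all
#' organs mechanistic with `alpha = 0.1`, `R = 0.5`, `beta_ear = 1`,
#' `gamma_e = gamma_a = 0`): it exercises every model path and preserves
#' between-modality orderings, but its absolute EAR/LAR values are not
#' literature estimates. Supply a transcribed literature registry via `path`
#' for absolute risk figures.
#'
#' @param path Optional YAML registry path; default is the packaged
#'   demonstration set.
#' @return A tibble with one row per organ and columns `organ`, `model`,
#'   `alpha`, `R`, `beta_ear`, `gamma_e`, `gamma_a`, `alpha_beta`, `source`.
#' @export
default_risk_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "risk_params_demo.yaml", package = "dvhrisk",
                        mustWork = TRUE)
  y <- yaml::read_yaml(path)
  names(y) <- canonical_structure(names(y))
  if (!"small_bowel" %in% names(y) && any(!c("kidneys", "pancreas") %in% names(y)))
    stop("registry must contain 'small_bowel' to clone kidneys/pancreas from")
  for (org in c("kidneys", "pancreas")) {
    if (!org %in% names(y)) {
      y[[org]] <- y[["small_bowel"]]
      y[[org]]$source <- paste0(y[[org]]$source, " (cloned from small_bowel)")
    }
  }
  tb <- dplyr::bind_rows(lapply(names(y), function(org) {
    b <- y[[org]]
    tibble::tibble(organ = org,
                   model = match.arg(b$model, c("linear", "bell", "plateau", "mechanistic")),
                   alpha = as.numeric(b$alpha), R = as.numeric(b$R),
                   beta_ear = as.numeric(b$beta_ear),
                   gamma_e = as.numeric(b$gamma_e),
                   gamma_a = as.numeric(b$gamma_a),
                   alpha_beta = as.numeric(b$alpha_beta %||% 3),
                   source = as.character(b$source %||% "unspecified"))
  }))
  stopifnot(all(tb$alpha >= 0), all(tb$R >= 0 & tb$R <= 1),
            all(tb$beta_ear >= 0))
  tb[order(match(tb$organ, risk_organs())), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The nine organs carrying secondary-cancer risk models
#'
#' Bone structures (femurs, pelvic ilium, sacrum, vertebral bodies) are
#' reported in dosimetry only; leukemia is not modelled (the pelvic-ilium
#' V10 is its dosimetric surrogate).
#'
#' @return Character vector of organ names.
#' @export
risk_organs <- function() {
  c("bladder", "large_bowel", "small_bowel", "spinal_cord", "kidneys",
    "liver", "pancreas", "rectum", "stomach")
}

#' General-population baseline cancer incidence
#'
#' SEER-based absolute incidence per 10,000 person-years for the eight
#' organs with population baselines, packaged for optional
#' relative-to-baseline reporting.
#'
#' @return A tibble with columns `organ` and `incidence_per_10k_py`.
#' @export
baseline_incidence <- function() {
  path <- system.file("extdata", "baseline_incidence.yaml", package = "dvhrisk",
                      mustWork = TRUE)
  y <- yaml::read_yaml(path)
  tibble::tibble(organ = canonical_structure(names(y)),
                 incidence_per_10k_py = vapply(y, as.numeric, numeric(1)))
}

#' Published per-organ cohort risk estimates
#'
#' The published per-organ EAR (per 10,000 person-years) and LAR (%) cohort
#' means for the 10-patient stage II seminoma planning comparison, for the
#' nine risk-modelled organs under each modality. These printed values are
#' inputs to the aggregation and reduction operations (the underlying
#' patient DVHs are not publicly available).
#'
#' @return A tibble with columns `organ`, `modality`, `ear`, `lar`.
#' @export
reference_risk_table <- function() {
  path <- system.file("extdata", "reference_cohort_risk.csv",
                      package = "dvhrisk", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Reporting rounding convention for risk totals
#'
#' Risk totals are displayed with one decimal at or above 2 and two decimals
#' below 2; published percent reductions are computed from totals rounded
#' this way, so the package mirrors that arithmetic when reporting.
#'
#' @param x Numeric vector.
#' @return Rounded vector.
#' @export
report_round <- function(x) ifelse(abs(x) >= 2, round(x, 1), round(x, 2))
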