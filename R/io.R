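#' Read DVHs from a CSV file
#'
#' The dialect is one UTF-8 CSV with header `structure,dose_gy,volume_cc,kind`
#' and one row per bin edge. `kind` is `"differential"` (each row: bin left
#' edge and the volume in the bin starting there; the final right edge is
#' inferred from the last edge spacing) or `"cumulative"` (each row: dose and
#' the volume receiving at least that dose). All rows of one structure must
#' share the same kind; mixed files (different kinds for different
#' structures) are allowed.
#'
#' @param path Path to the CSV file.
#' @return A named list of [dvh()] objects (canonical differential form),
#'   one per structure, named by structure.
#' @export
read_dvh_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("DVH file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("structure", "dose_gy", "volume_cc", "kind")
  if (!all(need %in% names(df)))
    stop(sprintf("DVH file %s must have columns %s", path,
                 paste(need, collapse = ", ")))
  if (!all(df$kind %in% c("cumulative", "differential"))) {
    bad <- which(!(df$kind %in% c("cumulative", "differential")))[1L]
    stop(sprintf("parse error in %s line %d: kind must be 'cumulative' or 'differential'",
                 path, bad + 1L))
  }
  bad <- which(!is.finite(df$dose_gy) | !is.finite(df$volume_cc))
  if (length(bad))
    stop(sprintf("parse error in %s line %d: non-numeric dose or volume",
                 path, bad[1L] + 1L))
  out <- list()
  for (s in unique(df$structure)) {
    rows <- df[df$structure == s, , drop = FALSE]
    kind <- unique(rows$kind)
    if (length(kind) != 1L)
      stop(sprintf("structure '%s' mixes cumulative and differential rows", s))
    if (any(rows$volume_cc < 0))
      stop(sprintf("negative volume for structure '%s' in %s", s, path))
    if (kind == "cumulative") {
      out[[s]] <- dvh_from_cumulative(s, rows$dose_gy, rows$volume_cc)
    } else {
      edges <- rows$dose_gy
      if (length(edges) < 2L)
        stop(sprintf("structure '%s': differential DVH needs >= 2 rows", s))
      w <- edges[length(edges)] - edges[length(edges) - 1L]
      out[[s]] <- dvh(s, edges = c(edges, edges[length(edges)] + w),
                      bin_volume = rows$volume_cc)
    }
  }
  out
}

#' Write DVHs to a CSV file
#'
#' @param dvhs A [dvh()] or named list of them.
#' @param path Output path.
#' @param kind `"differential"` (default; round-trips exactly through
#'   [read_dvh_csv()]) or `"cumulative"`.
#' @return `path`, invisibly.
#' @export
write_dvh_csv <- function(dvhs, path, kind = c("differential", "cumulative")) {
  kind <- match.arg(kind)
  if (is_dvh(dvhs)) dvhs <- stats::setNames(list(dvhs), dvhs$structure)
  rows <- lapply(dvhs, function(d) {
    if (kind == "differential") {
      data.frame(structure = d$structure,
                 dose_gy = d$edges[-length(d$edges)],
                 volume_cc = d$bin_volume, kind = kind)
    } else {
      cum <- to_cumulative(d)
      data.frame(structure = d$structure, dose_gy = cum$dose,
                 volume_cc = cum$volume_cc, kind = kind)
    }
  })
  df <- do.call(rbind, rows)
  # full precision so the differential round trip is exact
  df$dose_gy <- formatC(df$dose_gy, digits = 17, format = "g")
  df$volume_cc <- formatC(df$volume_cc, digits = 17, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Single-modality treatment plan record
#'
#' @param patient_id Patient label.
#' @param modality One of `"3D"`, `"VMAT"`, `"PBS"`.
#' @param prescription_dose Total prescription in GyRBE (30 for stage IIA,
#'   36 for IIB in this cohort).
#' @param n_fractions Number of fractions (15 / 18 here).
#' @param dvhs Named list of [dvh()] objects; must include a `"body"`
#'   structure.
#' @return An object of class `"plan_record"`.
#' @export
plan_record <- function(patient_id, modality, prescription_dose, n_fractions,
                        dvhs) {
  modality <- match.arg(modality, c("3D", "VMAT", "PBS"))
  stopifnot(prescription_dose > 0, n_fractions >= 1)
  dpf <- prescription_dose / n_fractions
  if (dpf < 1 || dpf > 3)
    warning(sprintf("dose per fraction %.2f GyRBE is outside the 1-3 GyRBE range of the modelled regimens", dpf))
  names(dvhs) <- canonical_structure(names(dvhs))
  if (!"body" %in% names(dvhs))
    stop("plan must include a 'body' structure")
  stopifnot(all(vapply(dvhs, is_dvh, logical(1))))
  structure(list(patient_id = patient_id, modality = modality,
                 prescription_dose = prescription_dose,
                 n_fractions = n_fractions, dvhs = dvhs),
            class = "plan_record")
}

# case-insensitive, whitespace-normalized structure matching key
canonical_structure <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", "_", x)
}

#' Patient record with one plan per modality
#'
#' All plans of one patient must share an identical structure set (matched
#' case-insensitively after whitespace normalization); a mismatch is an
#' error.
#'
#' @param patient_id Patient label.
#' @param age_at_treatment Age in years, in `[18, 70)`.
#' @param stage `"IIA"` or `"IIB"`.
#' @param plans Named list of [plan_record()] objects keyed by modality.
#' @return An object of class `"rt_patient"`.
#' @export
patient_record <- function(patient_id, age_at_treatment, stage, plans) {
  stage <- match.arg(stage, c("IIA", "IIB"))
  stopifnot(age_at_treatment >= 18, age_at_treatment < 70)
  ref <- sort(names(plans[[1L]]$dvhs))
  for (p in plans) {
    if (!identical(sort(names(p$dvhs)), ref))
      stop(sprintf("patient '%s': structure sets differ between modalities",
                   patient_id))
  }
  structure(list(patient_id = patient_id, age_at_treatment = age_at_treatment,
                 stage = stage, plans = plans),
            class = "rt_patient")
}

#' Write a cohort to a directory of CSV DVHs plus YAML metadata
#'
#' One subdirectory per patient containing `metadata.yaml` and one
#' differential DVH CSV per modality; round-trips through [read_cohort()].
#'
#' @param cohort List of [patient_record()] objects.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pt in cohort) {
    pdir <- file.path(dir, pt$patient_id)
    dir.create(pdir, showWarnings = FALSE)
    meta <- list(patient_id = pt$patient_id, age = pt$age_at_treatment,
                 stage = pt$stage, modalities = list())
    for (m in names(pt$plans)) {
      pl <- pt$plans[[m]]
      f <- sprintf("dvh_%s.csv", m)
      write_dvh_csv(pl$dvhs, file.path(pdir, f))
      meta$modalities[[m]] <- list(prescription_dose = pl$prescription_dose,
                                   n_fractions = pl$n_fractions,
                                   dvh_file = f)
    }
    yaml::write_yaml(meta, file.path(pdir, "metadata.yaml"))
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return List of [patient_record()] objects, ordered by patient id.
#' @export
read_cohort <- function(dir) {
  pdirs <- sort(list.dirs(dir, recursive = FALSE))
  if (!length(pdirs)) stop(sprintf("no patient directories under %s", dir))
  lapply(pdirs, function(pdir) {
    meta <- yaml::read_yaml(file.path(pdir, "metadata.yaml"))
    plans <- lapply(names(meta$modalities), function(m) {
      mm <- meta$modalities[[m]]
      plan_record(meta$patient_id, m, mm$prescription_dose, mm$n_fractions,
                  read_dvh_csv(file.path(pdir, mm$dvh_file)))
    })
    names(plans) <- names(meta$modalities)
    patient_record(meta$patient_id, meta$age, meta$stage, plans)
  })
}
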