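#' Apply the cohort exclusion rules
#'
#' Drops patient-days without an available SOFA score and drops entirely any
#' patient whose comorbidity data are unavailable, logging the count removed
#' for each reason. Patients left with zero retained days are also removed
#' from the patient table.
#'
#' @param patients Patient table (`patient_id`, `comorbidity_codes`, ...).
#' @param patient_days Patient-day table (`patient_id`, `sofa_score`, ...).
#' @return List with elements `patients`, `patient_days` (filtered) and
#'   `log` (data frame of `reason`, `n`).
#' @export
apply_exclusions <- function(patients, patient_days) {
  orphan <- setdiff(patient_days$patient_id, patients$patient_id)
  if (length(orphan)) {
    stop("patient-day rows reference absent patient(s): ",
         paste(utils::head(orphan, 5), collapse = ", "), call. = FALSE)
  }
  if (!"sofa_score" %in% names(patient_days) && nrow(patient_days) > 0) {
    patient_days$sofa_score <- sofa_score(patient_days)$sofa_score
  }
  n_day_missing_sofa <- if (nrow(patient_days)) sum(is.na(patient_days$sofa_score)) else 0L
  days <- patient_days[!is.na(patient_days$sofa_score), , drop = FALSE]

  no_comorb <- patients$patient_id[is.na(patients$comorbidity_codes)]
  n_pat_no_comorb <- length(no_comorb)
  n_day_no_comorb <- sum(days$patient_id %in% no_comorb)
  days <- days[!days$patient_id %in% no_comorb, , drop = FALSE]
  pats <- patients[!patients$patient_id %in% no_comorb, , drop = FALSE]

  empty <- setdiff(pats$patient_id, days$patient_id)
  pats <- pats[!pats$patient_id %in% empty, , drop = FALSE]

  log <- data.frame(
    reason = c("patient_days_missing_sofa", "patients_missing_comorbidity",
               "patient_days_of_excluded_patients",
               "patients_with_no_retained_days"),
    n = c(n_day_missing_sofa, n_pat_no_comorb, n_day_no_comorb, length(empty))
  )
  if (nrow(patient_days) == 0 && nrow(patients) == 0) {
    log <- log[0, , drop = FALSE]
  }
  rownames(days) <- NULL
  rownames(pats) <- NULL
  list(patients = pats, patient_days = days, log = log)
}

#' Per-patient maximum and minimum triage outcomes
#'
#' Collapses scored patient-days to one row per patient, taking the
#' componentwise maximum and minimum of the priority score, priority group,
#' SOFA score and SOFA points across all available days (the 8 audit
#' outcomes), plus the number of contributing days.
#'
#' @param scored_days Output of [score_cohort()] after [apply_exclusions()];
#'   rows with a missing priority score are not allowed.
#' @return Data frame with one row per patient: `patient_id`, `n_days`, and
#'   `max_`/`min_` columns for `priority_score`, `priority_group`,
#'   `sofa_score`, `sofa_points`.
#' @export
summarize_patients <- function(scored_days) {
  if (nrow(scored_days) == 0) stop("no patient-days to summarize", call. = FALSE)
  need <- c("patient_id", "priority_score", "priority_group", "sofa_score",
            "sofa_points")
  missing_cols <- setdiff(need, names(scored_days))
  if (length(missing_cols)) {
    stop("scored_days lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(scored_days[need])) {
    stop("scored_days contains missing outcomes; run apply_exclusions() first",
         call. = FALSE)
  }
  id <- factor(scored_days$patient_id,
               levels = unique(scored_days$patient_id))
  out <- data.frame(patient_id = levels(id),
                    n_days = as.integer(tabulate(id)))
  for (v in c("priority_score", "priority_group", "sofa_score", "sofa_points")) {
    x <- scored_days[[v]]
    out[[paste0("max_", v)]] <- as.integer(group_extreme(x, id, max))
    out[[paste0("min_", v)]] <- as.integer(group_extreme(x, id, min))
  }
  out
}

group_extreme <- function(x, id, fun) {
  vapply(split(x, id), fun, numeric(1), USE.NAMES = FALSE)
}
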