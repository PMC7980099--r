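#' Patient-level covariates for the audit
#'
#' Assembles the regression covariate table: demographics from the patient
#' table, plus `hospital` (the patient's hospital) and `covid_unit` (whether
#' the patient was ever cared for on a COVID-19 unit) lifted from the
#' patient-day table, and indicators for carrying at least one 5-year-tier
#' and at least one 1-year-tier comorbidity.
#'
#' @param patients Patient table.
#' @param patient_days Patient-day table with `hospital` and `covid_unit`.
#' @param config A [triage_config()] (for the comorbidity catalog).
#' @return Data frame keyed by `patient_id` with columns `race`,
#'   `ethnicity`, `sex`, `language`, `income_band`, `insurer`, `age_years`,
#'   `hospital`, `covid_unit`, `comorb_5yr`, `comorb_1yr`.
#' @export
patient_covariates <- function(patients, patient_days,
                               config = triage_config()) {
  out <- patients[intersect(c("patient_id", "race", "ethnicity", "sex",
                              "language", "income_band", "insurer",
                              "age_years"), names(patients))]
  idx <- match(out$patient_id, patient_days$patient_id)
  out$hospital <- patient_days$hospital[idx]
  covid_any <- tapply(as.logical(patient_days$covid_unit),
                      patient_days$patient_id, any)
  out$covid_unit <- as.logical(covid_any[out$patient_id])
  codes <- split_codes(patients$comorbidity_codes)
  tier <- stats::setNames(config$catalog$tier, config$catalog$code)
  out$comorb_5yr <- vapply(codes, function(cc) any(tier[cc] == "FIVE_YEAR"), FALSE)
  out$comorb_1yr <- vapply(codes, function(cc) any(tier[cc] == "ONE_YEAR"), FALSE)
  out
}

#' Reprioritization from including longer-term prognosis
#'
#' Compares, per patient, the triage group based on SOFA points alone
#' ([sofa_only_group()]) with the full priority group that also counts
#' comorbidities. A patient moves to *higher* priority when the full
#' algorithm assigns a strictly smaller group index, to *lower* priority
#' when strictly larger. Fractions are reported overall and per race and
#' ethnicity level.
#'
#' @param summaries Output of [summarize_patients()].
#' @param covariates Output of [patient_covariates()].
#' @param which `"max"` or `"min"`: which per-patient extremum to compare.
#' @return Data frame with columns `dimension` (`overall`/`race`/
#'   `ethnicity`), `level`, `n`, `frac_higher`, `frac_lower`,
#'   `frac_unchanged`; the three fractions sum to 1 in every row.
#' @export
reprioritization <- function(summaries, covariates, which = c("max", "min")) {
  extremum <- match.arg(which)
  dat <- merge(summaries, covariates, by = "patient_id")
  sofa_grp <- sofa_only_group(dat[[paste0(extremum, "_sofa_points")]])
  full_grp <- dat[[paste0(extremum, "_priority_group")]]
  move <- ifelse(full_grp < sofa_grp, "higher",
                 ifelse(full_grp > sofa_grp, "lower", "unchanged"))
  frac_row <- function(dimension, level, idx) {
    m <- move[idx]
    n <- length(m)
    data.frame(dimension = dimension, level = level, n = n,
               frac_higher = mean(m == "higher"),
               frac_lower = mean(m == "lower"),
               frac_unchanged = mean(m == "unchanged"))
  }
  rows <- list(frac_row("overall", "all", seq_along(move)))
  for (l in covariate_levels()$race) {
    idx <- which(dat$race == l)
    if (length(idx)) rows[[length(rows) + 1]] <- frac_row("race", l, idx)
  }
  for (l in covariate_levels()$ethnicity) {
    idx <- which(dat$ethnicity == l)
    if (length(idx)) rows[[length(rows) + 1]] <- frac_row("ethnicity", l, idx)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full disparity audit
#'
#' One call from raw cohort tables to the complete audit: exclusions,
#' per-day scoring, per-patient max/min summaries, descriptive comparisons
#' across maximum and minimum priority groups, Poisson IRR models for all
#' 8 outcomes (complete-case primary) plus the unknown-category and
#' no-socioeconomic-covariate sensitivity variants for the two coprimary
#' outcomes, and the reprioritization comparison.
#'
#' @param patients,patient_days Raw cohort tables (see [read_cohort()]).
#' @param config A [triage_config()].
#' @param robust Report robust (sandwich) standard errors in IRR tables.
#' @return Object of class `csc_audit`: a list with `exclusions`,
#'   `scored_days`, `summaries`, `covariates`, `descriptives_max`,
#'   `descriptives_min`, `irr_fits` (named list of [fit_irr()] objects),
#'   `sensitivity_fits`, `reprioritization_max`, `reprioritization_min`.
#' @export
csc_audit <- function(patients, patient_days, config = triage_config(),
                      robust = FALSE) {
  excl <- apply_exclusions(patients, patient_days)
  scored <- score_cohort(excl$patients, excl$patient_days, config)
  summaries <- summarize_patients(scored)
  covariates <- patient_covariates(excl$patients, excl$patient_days, config)

  outcomes <- as.vector(outer(c("max_", "min_"),
                              c("priority_score", "priority_group",
                                "sofa_score", "sofa_points"), paste0))
  irr_fits <- lapply(stats::setNames(outcomes, outcomes), function(o)
    fit_irr(summaries, covariates, outcome = o, robust = robust))
  sens <- list()
  for (o in c("max_priority_score", "min_priority_score")) {
    sens[[paste0(o, "_unknown")]] <-
      fit_irr(summaries, covariates, o, analysis = "unknown_category",
              robust = robust)
    sens[[paste0(o, "_no_ses")]] <-
      fit_irr(summaries, covariates, o, analysis = "no_ses", robust = robust)
  }

  out <- list(
    exclusions = excl$log,
    scored_days = scored,
    summaries = summaries,
    covariates = covariates,
    descriptives_max = descriptive_tests(summaries, covariates, "max"),
    descriptives_min = descriptive_tests(summaries, covariates, "min"),
    irr_fits = irr_fits,
    sensitivity_fits = sens,
    reprioritization_max = reprioritization(summaries, covariates, "max"),
    reprioritization_min = reprioritization(summaries, covariates, "min"),
    config = config
  )
  class(out) <- "csc_audit"
  out
}

#' @export
print.csc_audit <- function(x, ...) {
  cat(sprintf("CSC triage disparity audit: %d patients, %d patient-days\n",
              nrow(x$summaries), nrow(x$scored_days)))
  if (nrow(x$exclusions)) {
    cat("Exclusions:\n")
    for (i in seq_len(nrow(x$exclusions))) {
      cat(sprintf("  %s: %d\n", x$exclusions$reason[i], x$exclusions$n[i]))
    }
  }
  grp <- table(factor(x$summaries$max_priority_group, levels = 1:3))
  cat(sprintf("Maximum priority groups: 1: %d, 2: %d, 3: %d\n",
              grp[1], grp[2], grp[3]))
  cat("\nPrimary model, maximum priority score:\n")
  print(x$irr_fits$max_priority_score)
  invisible(x)
}
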