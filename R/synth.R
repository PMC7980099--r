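#' Configuration for the synthetic two-hospital cohort generator
#'
#' The defaults emulate the published structure of the study cohort the
#' audit was designed for: n = 1127 patients across a tertiary and a
#' quaternary hospital, the printed race / ethnicity / sex / language /
#' income / insurer marginals, comorbidity-tier prevalences of 36.2%
#' (5-year) and 19.3% (1-year), and a days-of-data law with median 3 and
#' IQR 2-7 (a shifted negative binomial, `1 + NB(size = 0.7, mu = 4.4)`).
#'
#' Severity is generated at the patient level: each patient's peak daily
#' SOFA score is Poisson with log-mean `log_peak_mean` plus any injected
#' race/ethnicity effects (`disparity_log_irr`), so the audit's Poisson
#' model for the maximum SOFA score is correctly specified and injected
#' log-IRRs are recoverable. Daily scores are the peak minus non-negative
#' autocorrelated (AR(1)) deviations, giving within-patient day-to-day
#' correlation.
#'
#' Covariates are drawn independently of each other and of severity by
#' default (a null cohort); `disparity_log_irr` injects severity effects
#' and `comorbidity_logit_shift` couples comorbidity prevalence to race or
#' ethnicity, which is how a higher comorbidity burden in a subgroup is
#' simulated.
#'
#' @param n_patients Number of patients.
#' @param race_marginals,ethnicity_marginals,sex_marginals,
#'   language_marginals,income_marginals,insurer_marginals Named probability
#'   vectors over the levels of [covariate_levels()]; each must sum to 1.
#' @param prevalence_5yr,prevalence_1yr Probabilities of carrying at least
#'   one comorbidity of each tier (drawn independently; a patient may have
#'   both).
#' @param days_nb_size,days_nb_mu Negative-binomial parameters of the
#'   days-of-data law (days = 1 + NB).
#' @param log_peak_mean Baseline log of the expected peak daily SOFA score.
#' @param ar_rho AR(1) autocorrelation of the latent daily deviation path.
#' @param drop_scale Scale (SOFA units per latent SD) of the deviations
#'   below the peak.
#' @param missing_sofa_day_rate Fraction of patient-days whose SOFA score is
#'   unavailable.
#' @param missing_comorbidity_rate Fraction of patients whose comorbidity
#'   data are unavailable.
#' @param age_mean,age_sd,age_range Normal age distribution (years), clipped
#'   to `age_range`.
#' @param age_missing_rate Fraction of patients with missing age.
#' @param hospital_tertiary Probability a patient is at the tertiary
#'   hospital.
#' @param covid_unit_rate Probability a patient is cared for on a COVID-19
#'   unit.
#' @param disparity_log_irr List with named numeric vectors `race` and
#'   `ethnicity`: additive log effects on the latent severity (default all
#'   zero, the null).
#' @param comorbidity_logit_shift Same shape: additive shifts on the logit
#'   of both comorbidity prevalences.
#' @param short_term_recovery_rate,essential_function_rate Prevalence of the
#'   two tiebreak flags.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(
    n_patients = 1127,
    race_marginals = c(White = 711, Black = 323, Asian = 8,
                       Multiracial = 31, Unknown = 54) / 1127,
    ethnicity_marginals = c(NonHispanic = 480, Hispanic = 611,
                            Unknown = 36) / 1127,
    sex_marginals = c(male = 607, female = 509, Unknown = 11) / 1127,
    language_marginals = c(English = 591, Spanish = 489, Other = 35,
                           Unknown = 12) / 1127,
    income_marginals = stats::setNames(c(219, 546, 236, 71, 55) / 1127,
                                       covariate_levels()$income_band),
    insurer_marginals = stats::setNames(c(360, 589, 153, 25) / 1127,
                                        covariate_levels()$insurer),
    prevalence_5yr = 0.362,
    prevalence_1yr = 0.193,
    days_nb_size = 0.7,
    days_nb_mu = 4.4,
    log_peak_mean = log(4.5),
    ar_rho = 0.7,
    drop_scale = 1.5,
    missing_sofa_day_rate = 0.05,
    missing_comorbidity_rate = 0.02,
    age_mean = 62.7,
    age_sd = 16.3,
    age_range = c(18, 105),
    age_missing_rate = 3 / 1127,
    hospital_tertiary = 675 / 1127,
    covid_unit_rate = 690 / 1127,
    disparity_log_irr = list(
      race = stats::setNames(numeric(5), covariate_levels()$race),
      ethnicity = stats::setNames(numeric(3), covariate_levels()$ethnicity)),
    comorbidity_logit_shift = list(
      race = stats::setNames(numeric(5), covariate_levels()$race),
      ethnicity = stats::setNames(numeric(3), covariate_levels()$ethnicity)),
    short_term_recovery_rate = 0.2,
    essential_function_rate = 0.05) {
  cfg <- as.list(environment())
  lv <- covariate_levels()
  marg <- list(race = race_marginals, ethnicity = ethnicity_marginals,
               sex = sex_marginals, language = language_marginals,
               income_band = income_marginals, insurer = insurer_marginals)
  for (v in names(marg)) {
    p <- marg[[v]]
    if (length(p) != length(lv[[v]]) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-6) {
      stop(sprintf("%s marginals must be a probability vector over %d levels",
                   v, length(lv[[v]])), call. = FALSE)
    }
  }
  for (r in c("prevalence_5yr", "prevalence_1yr", "missing_sofa_day_rate",
              "missing_comorbidity_rate", "age_missing_rate",
              "hospital_tertiary", "covid_unit_rate",
              "short_term_recovery_rate", "essential_function_rate")) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1) {
      stop(r, " must be in [0, 1]", call. = FALSE)
    }
  }
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  structure(cfg, class = "synth_config")
}

#' Configuration emulating the published study cohort
#'
#' Convenience wrapper: [synth_config()] with all defaults, i.e. the
#' printed cohort marginals (n = 1127; race 63.1 / 28.7 / 0.7 / 2.8 / 4.8%;
#' ethnicity 42.6 / 54.2 / 3.2%; 53.9% men; 61.2% COVID unit; 59.9%
#' tertiary hospital; comorbidity prevalences 36.2% and 19.3%) and no
#' injected disparity.
#'
#' @param ... Overrides passed to [synth_config()].
#' @return A `synth_config`.
#' @export
study_profile <- function(...) synth_config(...)

#' Generate a synthetic cohort
#'
#' Draws a patient table and a patient-day table from a [synth_config()],
#' together with a truth record holding every generating parameter and the
#' per-patient latent severity. Output is deterministic for a fixed seed.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; all randomness flows from it.
#' @return List of class `synth_cohort` with elements `patients`,
#'   `patient_days`, `truth`.
#' @export
#' @examples
#' coh <- synth_cohort(synth_config(n_patients = 50), seed = 1)
#' head(coh$patient_days)
synth_cohort <- function(config = synth_config(), seed = 1L) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(as.integer(seed), generate_cohort(config, seed))
}

generate_cohort <- function(cfg, seed) {
  n <- cfg$n_patients
  lv <- covariate_levels()
  draw <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  patients <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    race = draw(cfg$race_marginals),
    ethnicity = draw(cfg$ethnicity_marginals),
    sex = draw(cfg$sex_marginals),
    language = draw(cfg$language_marginals),
    income_band = draw(cfg$income_marginals),
    insurer = draw(cfg$insurer_marginals)
  )
  age <- pmin(pmax(stats::rnorm(n, cfg$age_mean, cfg$age_sd),
                   cfg$age_range[1]), cfg$age_range[2])
  age[stats::runif(n) < cfg$age_missing_rate] <- NA
  patients$age_years <- round(age, 1)

  shift <- cfg$comorbidity_logit_shift
  sh <- shift$race[patients$race] + shift$ethnicity[patients$ethnicity]
  p1 <- stats::plogis(stats::qlogis(cfg$prevalence_1yr) + sh)
  p5 <- stats::plogis(stats::qlogis(cfg$prevalence_5yr) + sh)
  has_1yr <- stats::runif(n) < p1
  has_5yr <- stats::runif(n) < p5
  catalog <- comorbidity_catalog()
  codes_5 <- catalog$code[catalog$tier == "FIVE_YEAR"]
  codes_1 <- catalog$code[catalog$tier == "ONE_YEAR"]
  pick5 <- sample(codes_5, n, replace = TRUE)
  pick1 <- sample(codes_1, n, replace = TRUE)
  codes <- character(n)
  codes[has_5yr] <- pick5[has_5yr]
  codes[has_1yr] <- ifelse(nzchar(codes[has_1yr]),
                           paste(codes[has_1yr], pick1[has_1yr], sep = ";"),
                           pick1[has_1yr])
  codes[stats::runif(n) < cfg$missing_comorbidity_rate] <- NA
  patients$comorbidity_codes <- codes
  patients$short_term_recovery_comorbidity <-
    stats::runif(n) < cfg$short_term_recovery_rate
  patients$essential_function <- stats::runif(n) < cfg$essential_function_rate

  hospital <- ifelse(stats::runif(n) < cfg$hospital_tertiary,
                     "tertiary", "quaternary")
  covid_unit <- stats::runif(n) < cfg$covid_unit_rate

  n_days <- 1L + stats::rnbinom(n, size = cfg$days_nb_size, mu = cfg$days_nb_mu)

  disp <- cfg$disparity_log_irr
  eta <- cfg$log_peak_mean + disp$race[patients$race] +
    disp$ethnicity[patients$ethnicity]
  peak <- pmin(stats::rpois(n, exp(eta)), 24L)

  total <- sum(n_days)
  pid_day <- rep(seq_len(n), n_days)
  day_idx <- sequence(n_days)
  # one long AR(1) path, stationary unit variance; deviations are measured
  # relative to each patient's own maximum, so boundary carryover is inert
  z <- as.numeric(stats::filter(stats::rnorm(total, 0, sqrt(1 - cfg$ar_rho^2)),
                                cfg$ar_rho, method = "recursive"))
  zmax <- stats::ave(z, pid_day, FUN = max)
  sofa <- pmax(peak[pid_day] - as.integer(round(cfg$drop_scale * (zmax - z))), 0L)
  sofa[stats::runif(total) < cfg$missing_sofa_day_rate] <- NA

  patient_days <- data.frame(
    patient_id = patients$patient_id[pid_day],
    date = as.character(as.Date("2020-05-16") + day_idx - 1L),
    hospital = hospital[pid_day],
    covid_unit = covid_unit[pid_day],
    sofa_score = as.integer(sofa)
  )
  truth <- list(seed = seed, config = cfg,
                latent = data.frame(patient_id = patients$patient_id,
                                    log_peak = as.numeric(eta),
                                    peak_sofa = peak, n_days = n_days))
  structure(list(patients = patients, patient_days = patient_days,
                 truth = truth), class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patients, %d patient-days (seed %s)\n",
              nrow(x$patients), nrow(x$patient_days), x$truth$seed))
  invisible(x)
}
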