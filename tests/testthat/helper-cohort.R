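# Small in-code fixtures shared across test files.

# A hand-built three-patient cohort with known triage arithmetic.
tiny_patients <- function() {
  data.frame(
    patient_id = c("A", "B", "C"),
    race = c("White", "Black", "White"),
    ethnicity = c("NonHispanic", "Hispanic", "Hispanic"),
    sex = c("male", "female", "male"),
    language = c("English", "Spanish", "English"),
    income_band = c("<25k", "25-<50k", ">=75k"),
    insurer = c("Commercial", "Medicare/Medicaid", "None"),
    age_years = c(40, 70, 55),
    comorbidity_codes = c("", "moderate_dementia", "severe_burns"),
    short_term_recovery_comorbidity = c(FALSE, TRUE, FALSE),
    essential_function = c(FALSE, FALSE, TRUE)
  )
}

tiny_days <- function() {
  data.frame(
    patient_id = rep(c("A", "B", "C"), times = c(3, 2, 1)),
    date = as.character(as.Date("2020-06-01") + c(0:2, 0:1, 0)),
    hospital = c(rep("tertiary", 3), rep("quaternary", 2), "tertiary"),
    covid_unit = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    sofa_score = c(4L, 7L, 5L, 10L, 12L, NA)
  )
}

# Patient-level covariate table with no Unknowns, for model tests.
sim_covariates <- function(n, seed) {
  withr::with_seed(seed, {
    data.frame(
      patient_id = sprintf("S%05d", seq_len(n)),
      race = sample(c("White", "Black", "Asian", "Multiracial"), n, TRUE,
                    prob = c(0.6, 0.3, 0.05, 0.05)),
      ethnicity = sample(c("NonHispanic", "Hispanic"), n, TRUE),
      sex = sample(c("male", "female"), n, TRUE),
      language = sample(c("English", "Spanish", "Other"), n, TRUE,
                        prob = c(0.5, 0.4, 0.1)),
      income_band = sample(c("<25k", "25-<50k", "50-<75k", ">=75k"), n, TRUE),
      insurer = sample(c("Medicare/Medicaid", "Commercial", "None"), n, TRUE),
      age_years = round(runif(n, 20, 90), 1),
      hospital = sample(c("tertiary", "quaternary"), n, TRUE),
      covid_unit = runif(n) < 0.6
    )
  })
}

# Summaries table whose outcome is drawn from the Poisson regression model
# itself (log link), for parameter-recovery tests.
sim_model_summaries <- function(covariates, beta0, beta_black, seed,
                                outcome = "max_priority_score") {
  withr::with_seed(seed, {
    mu <- exp(beta0 + beta_black * (covariates$race == "Black"))
    out <- data.frame(patient_id = covariates$patient_id)
    out[[outcome]] <- rpois(nrow(covariates), mu)
    out
  })
}
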