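test_that("generation is bit-identical for a fixed seed", {
  cfg <- synth_config(n_patients = 200)
  a <- synth_cohort(cfg, seed = 7)
  b <- synth_cohort(cfg, seed = 7)
  expect_identical(a$patients, b$patients)
  expect_identical(a$patient_days, b$patient_days)
  c <- synth_cohort(cfg, seed = 8)
  expect_false(identical(a$patient_days, c$patient_days))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(synth_cohort(synth_config(n_patients = 20), seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(race_marginals = c(0.5, 0.5)), "probability")
  expect_error(synth_config(race_marginals = c(0.5, 0.3, 0.1, 0.05, 0.2)),
               "probability")
  expect_error(synth_config(missing_sofa_day_rate = 1.2), "0, 1")
  expect_error(synth_config(n_patients = 0), "n_patients")
})

test_that("empirical marginals converge to configured marginals", {
  coh <- synth_cohort(synth_config(n_patients = 50000), seed = 13)
  p <- coh$patients
  cfg <- synth_config()
  race_frac <- prop.table(table(p$race))[names(cfg$race_marginals)]
  expect_true(all(abs(race_frac - cfg$race_marginals) < 0.01))
  eth_frac <- prop.table(table(p$ethnicity))[names(cfg$ethnicity_marginals)]
  expect_true(all(abs(eth_frac - cfg$ethnicity_marginals) < 0.01))

  has_code <- !is.na(p$comorbidity_codes)
  catalog <- comorbidity_catalog()
  one_yr <- catalog$code[catalog$tier == "ONE_YEAR"]
  got_1yr <- vapply(strsplit(p$comorbidity_codes[has_code], ";"),
                    function(cc) any(cc %in% one_yr), FALSE)
  expect_lt(abs(mean(got_1yr) - cfg$prevalence_1yr), 0.01)
  expect_lt(abs(mean(p$patient_id %in%
                       coh$patient_days$patient_id[coh$patient_days$hospital ==
                                                     "tertiary"]) -
                  cfg$hospital_tertiary), 0.01)
})

test_that("days of data follow the configured duration law (median 3, IQR 2-7)", {
  coh <- synth_cohort(synth_config(n_patients = 50000), seed = 17)
  n_days <- table(coh$patient_days$patient_id)
  q <- quantile(as.integer(n_days), c(0.25, 0.5, 0.75), type = 1)
  expect_identical(as.integer(q), c(2L, 3L, 7L))
})

test_that("universal 1-year comorbidity forces minimum priority score of 5", {
  cfg <- synth_config(n_patients = 150, prevalence_1yr = 1,
                      missing_comorbidity_rate = 0, missing_sofa_day_rate = 0)
  coh <- synth_cohort(cfg, seed = 3)
  scored <- score_cohort(coh$patients, coh$patient_days)
  expect_true(all(scored$comorbidity_points == 4L))
  expect_true(all(scored$priority_score >= 5L))
})

test_that("SOFA trajectories stay in range and the truth record matches the draw", {
  coh <- synth_cohort(synth_config(n_patients = 400,
                                   missing_sofa_day_rate = 0), seed = 5)
  s <- coh$patient_days$sofa_score
  expect_true(all(s >= 0 & s <= 24))
  observed_max <- tapply(s, coh$patient_days$patient_id, max)
  lat <- coh$truth$latent
  expect_identical(as.integer(observed_max[lat$patient_id]),
                   as.integer(lat$peak_sofa))
  expect_identical(as.integer(table(coh$patient_days$patient_id)[lat$patient_id]),
                   as.integer(lat$n_days))
})

test_that("injected severity effects shift the affected subgroup's SOFA scores", {
  disp <- list(race = c(White = 0, Black = 0.4, Asian = 0, Multiracial = 0,
                        Unknown = 0),
               ethnicity = c(NonHispanic = 0, Hispanic = 0, Unknown = 0))
  coh <- synth_cohort(synth_config(n_patients = 4000,
                                   disparity_log_irr = disp,
                                   missing_sofa_day_rate = 0), seed = 9)
  lat <- merge(coh$truth$latent, coh$patients, by = "patient_id")
  ratio <- mean(lat$peak_sofa[lat$race == "Black"]) /
    mean(lat$peak_sofa[lat$race == "White"])
  expect_lt(abs(ratio - exp(0.4)), 0.1)
})
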