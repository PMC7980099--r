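test_that("a constant outcome yields IRRs of exactly 1", {
  cov <- sim_covariates(300, seed = 31)
  summ <- data.frame(patient_id = cov$patient_id, max_priority_score = 1L)
  fit <- fit_irr(summ, cov)
  tab <- irr_table(fit)
  expect_equal(tab$irr, rep(1, nrow(tab)), tolerance = 1e-6)
})

test_that("the fit matches an independently specified glm", {
  cov <- sim_covariates(500, seed = 32)
  summ <- sim_model_summaries(cov, beta0 = 1, beta_black = 0.2, seed = 33)
  fit <- fit_irr(summ, cov)
  dat <- merge(summ, cov, by = "patient_id")
  dat$race <- factor(dat$race, levels = c("White", "Black", "Asian", "Multiracial"))
  oracle <- glm(max_priority_score ~ race + factor(ethnicity) + factor(sex) +
                  factor(language) + factor(income_band) + factor(insurer) +
                  factor(hospital) + age_years + covid_unit,
                data = dat, family = poisson())
  expect_equal(unname(coef(fit)[["raceBlack"]]),
               unname(coef(oracle)[["raceBlack"]]), tolerance = 1e-10)
  expect_equal(unname(coef(fit)[["age_years"]]),
               unname(coef(oracle)[["age_years"]]), tolerance = 1e-10)
})

test_that("an injected race effect is recovered from model-simulated data", {
  ests <- sapply(1:20, function(r) {
    cov <- sim_covariates(2000, seed = 300 + r)
    summ <- sim_model_summaries(cov, beta0 = 1, beta_black = 0.2,
                                seed = 400 + r)
    tab <- irr_table(fit_irr(summ, cov))
    tab$irr[tab$covariate == "race" & tab$level == "Black"]
  })
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - exp(0.2)), 3 * mc_se)
})

test_that("interval endpoints bracket the estimate and reference rows are marked", {
  cov <- sim_covariates(400, seed = 35)
  summ <- sim_model_summaries(cov, beta0 = 1, beta_black = 0, seed = 36)
  for (robust in c(FALSE, TRUE)) {
    tab <- irr_table(fit_irr(summ, cov, robust = robust))
    est <- tab[!tab$reference, ]
    expect_true(all(est$ci_lo <= est$irr & est$irr <= est$ci_hi))
    ref <- tab[tab$reference, ]
    expect_true(all(ref$irr == 1))
    expect_setequal(ref$covariate,
                    c("race", "ethnicity", "sex", "language", "income_band",
                      "insurer", "hospital"))
  }
})

test_that("with no unknowns the unknown-category analysis coincides with the primary", {
  cov <- sim_covariates(500, seed = 37)
  summ <- sim_model_summaries(cov, beta0 = 1, beta_black = 0.1, seed = 38)
  f1 <- fit_irr(summ, cov)
  f2 <- fit_irr(summ, cov, analysis = "unknown_category")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
  expect_identical(nobs(f1), nobs(f2))
})

test_that("unknowns with extreme outcomes pull the sensitivity fit away from the primary", {
  cov <- sim_covariates(1000, seed = 39)
  summ <- sim_model_summaries(cov, beta0 = 0.7, beta_black = 0, seed = 40)
  # hide income for 30% of patients; among the hidden, inflate only the
  # outcomes of female patients. The complete-case fit never sees those
  # patients, so its sex IRR stays near 1; the unknown-category fit keeps
  # them and must attribute the inflation to the female level.
  hide <- withr::with_seed(41, runif(nrow(cov)) < 0.3)
  cov$income_band[hide] <- "Unknown"
  bump <- hide & cov$sex == "female"
  summ$max_priority_score[bump] <- summ$max_priority_score[bump] + 5L
  get_female <- function(fit) {
    tab <- irr_table(fit)
    tab$irr[tab$covariate == "sex" & tab$level == "female"]
  }
  irr_primary <- get_female(fit_irr(summ, cov))
  irr_sens <- get_female(fit_irr(summ, cov, analysis = "unknown_category"))
  expect_lt(abs(irr_primary - 1), 0.15)
  expect_gt(irr_sens, irr_primary + 0.2)
})

test_that("dropping independent SES covariates leaves the race estimate unchanged", {
  # Poisson log-link estimates are collapsible over independent covariates
  # with null effects; at n = 2000 refit noise is well under 0.02 on the
  # log scale (measured spread ~0.002)
  cov <- sim_covariates(2000, seed = 42)
  summ <- sim_model_summaries(cov, beta0 = 1, beta_black = 0.15, seed = 43)
  b1 <- coef(fit_irr(summ, cov))[["raceBlack"]]
  b2 <- coef(fit_irr(summ, cov, analysis = "no_ses"))[["raceBlack"]]
  expect_lt(abs(b1 - b2), 0.02)
  tab <- irr_table(fit_irr(summ, cov, analysis = "no_ses"))
  expect_false(any(tab$covariate %in% c("income_band", "insurer")))
})

test_that("perfectly collinear covariates raise a named error", {
  cov <- sim_covariates(300, seed = 44)
  cov$language <- ifelse(cov$sex == "male", "English", "Spanish")
  summ <- sim_model_summaries(cov, beta0 = 1, beta_black = 0, seed = 45)
  expect_error(fit_irr(summ, cov), "collinear")
})

test_that("robust and model-based standard errors differ on non-Poisson outcomes", {
  cov <- sim_covariates(800, seed = 46)
  # strongly underdispersed outcome: constant 2 plus a rare bump
  summ <- data.frame(patient_id = cov$patient_id,
                     max_priority_score = 2L +
                       withr::with_seed(47, rbinom(800, 1, 0.05)))
  fit <- fit_irr(summ, cov)
  t_model <- irr_table(fit, robust = FALSE)
  t_robust <- irr_table(fit, robust = TRUE)
  w_model <- t_model$ci_hi - t_model$ci_lo
  w_robust <- t_robust$ci_hi - t_robust$ci_lo
  ok <- !t_model$reference
  # underdispersion makes model-based intervals conservative
  expect_gt(median(w_model[ok] / w_robust[ok]), 1.5)
})
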