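test_that("SOFA points follow the policy bands", {
  expect_identical(sofa_points(4), 1L)
  expect_identical(sofa_points(10), 3L)
  expect_identical(sofa_points(24), 4L)
  expect_identical(sofa_points(c(0, 5, 6, 8, 9, 11, 12)),
                   c(1L, 1L, 2L, 2L, 3L, 3L, 4L))
  expect_error(sofa_points(25), "0, 24")
  expect_error(sofa_points(-1), "0, 24")
})

test_that("comorbidity points use the single worst tier, never a sum", {
  expect_identical(comorbidity_points(character(0)), 0L)
  expect_identical(comorbidity_points("moderate_dementia"), 2L)
  expect_identical(
    comorbidity_points(list(c("moderate_dementia", "end_stage_kidney_disease",
                              "metastatic_stage_iv_cancer", "severe_burns",
                              "cardiac_arrest"))), 4L)
  expect_error(comorbidity_points("gout"), "gout")
})

test_that("priority score is the exact sum and covers 1 through 8", {
  expect_identical(priority_score(1, 0), 1L)
  expect_identical(priority_score(4, 4), 8L)
  expect_identical(priority_score(3, 2), 5L)
  grid <- expand.grid(sp = 1:4, cp = c(0L, 2L, 4L))
  scores <- priority_score(grid$sp, grid$cp)
  expect_setequal(scores, 1:8)
  expect_error(priority_score(5, 0))
  expect_error(priority_score(1, 3))
})

test_that("priority groups consolidate scores monotonically and are configurable", {
  expect_identical(priority_group(1:8), c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 3L))
  expect_identical(priority_group(2), 1L)
  expect_identical(priority_group(5), 2L)
  expect_identical(priority_group(8), 3L)
  expect_error(priority_group(0))
  expect_error(priority_group(9))
  alt <- triage_config(group_map = c(1, 1, 2, 2, 2, 3, 3, 3))
  expect_identical(priority_group(3, alt), 2L)
  expect_error(triage_config(group_map = c(1, 2, 1, 2, 2, 3, 3, 3)),
               "non-decreasing")
})

test_that("SOFA-only grouping combines points 3 and 4", {
  expect_identical(sofa_only_group(1:4), c(1L, 2L, 3L, 3L))
})

test_that("comorbidity inclusion can move relative priority in either direction", {
  # a patient with SOFA points 2 and no comorbidity rises to group 1 under
  # the full algorithm but sits in group 2 under SOFA-only grouping
  full <- priority_group(priority_score(2, 0))
  expect_lt(full, sofa_only_group(2))
  # while a 1-year comorbidity can push a low-SOFA patient down
  expect_gt(priority_group(priority_score(1, 4)), sofa_only_group(1))
  # and adding a comorbidity never decreases the score itself
  expect_true(all(priority_score(1:4, 2) >= priority_score(1:4, 0)))
  expect_true(all(priority_score(1:4, 4) >= priority_score(1:4, 2)))
})

profile_grid <- function() {
  g <- expand.grid(priority_group = 1:2, priority_score = c(2L, 5L),
                   short_term_recovery_comorbidity = c(FALSE, TRUE),
                   age_years = c(40, 70), essential_function = c(FALSE, TRUE))
  split(g, seq_len(nrow(g)))
}

test_that("tiebreak cascade follows the policy order", {
  a <- list(priority_group = 1, priority_score = 2)
  b <- list(priority_group = 2, priority_score = 2)
  expect_identical(tiebreak_compare(a, b), "a_first")
  young <- list(priority_group = 1, priority_score = 2, age_years = 40)
  old <- list(priority_group = 1, priority_score = 2, age_years = 70)
  expect_identical(tiebreak_compare(young, old), "a_first")
  expect_identical(tiebreak_compare(old, young), "b_first")
  noco <- list(priority_group = 1, priority_score = 2, age_years = 70,
               short_term_recovery_comorbidity = FALSE)
  withco <- list(priority_group = 1, priority_score = 2, age_years = 40,
                 short_term_recovery_comorbidity = TRUE)
  expect_identical(tiebreak_compare(noco, withco), "a_first")
  ess <- list(priority_group = 1, priority_score = 2, age_years = 40,
              essential_function = TRUE)
  non <- list(priority_group = 1, priority_score = 2, age_years = 40)
  expect_identical(tiebreak_compare(ess, non), "a_first")
  lo <- list(priority_group = 1, priority_score = 1, age_years = 40)
  hi <- list(priority_group = 1, priority_score = 3, age_years = 40)
  expect_identical(tiebreak_compare(lo, hi), "a_first")
  expect_identical(tiebreak_compare(a, a), "tie")
})

test_that("tiebreak comparison is a strict weak ordering on an enumerated grid", {
  profs <- profile_grid()
  n <- length(profs)
  cmp <- matrix("", n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    cmp[i, j] <- tiebreak_compare(profs[[i]], profs[[j]])
  }
  # antisymmetry up to tie
  for (i in seq_len(n)) for (j in seq_len(n)) {
    expect_identical(cmp[i, j],
                     switch(cmp[j, i], a_first = "b_first",
                            b_first = "a_first", tie = "tie"))
  }
  # transitivity of strict precedence
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (cmp[i, j] == "a_first" && cmp[j, k] == "a_first") {
      expect_identical(cmp[i, k], "a_first")
    }
  }
})

random_cohort_day <- function(n, seed) {
  withr::with_seed(seed, {
    sp <- sample(1:4, n, TRUE)
    cp <- sample(c(0L, 2L, 4L), n, TRUE)
    score <- priority_score(sp, cp)
    data.frame(patient_id = sprintf("P%02d", seq_len(n)),
               priority_score = score,
               priority_group = priority_group(score),
               short_term_recovery_comorbidity = runif(n) < 0.3,
               age_years = sample(c(30, 50, 70), n, TRUE),
               essential_function = runif(n) < 0.2)
  })
}

test_that("allocation respects scarcity, ordering and the seeded lottery", {
  day <- random_cohort_day(3, 1)
  expect_true(all(allocate(day, 5)$allocated))
  expect_error(allocate(day, -1), "non-negative")

  twins <- data.frame(patient_id = c("X", "Y"), priority_score = 2L,
                      priority_group = 1L, age_years = 50)
  first <- allocate(twins, 1, seed = 11)
  again <- allocate(twins, 1, seed = 11)
  expect_identical(first$patient_id, again$patient_id)
  expect_identical(sum(first$allocated), 1L)

  distinct <- withr::with_seed(7, data.frame(patient_id = letters[1:8],
                                             priority_score = sample(1:8),
                                             age_years = 50))
  distinct$priority_group <- priority_group(distinct$priority_score)
  res <- allocate(distinct, 4, seed = 3)
  expect_setequal(res$patient_id[res$allocated],
                  distinct$patient_id[order(distinct$priority_score)][1:4])
  expect_identical(sum(res$allocated), 4L)
})
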