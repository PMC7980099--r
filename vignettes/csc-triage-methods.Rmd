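---
title: "Methods: triage scoring, the disparity audit, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triage scoring, the disparity audit, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csctriage)
```

## The allocation algorithm

Crisis standards of care (CSC) govern how a hospital allocates life-saving
resources — ventilators in particular — when demand exceeds supply. The
policy implemented here scores every at-risk patient every day on two axes:

* **Short-term prognosis**: the daily Sequential Organ Failure Assessment
  (SOFA) score (0–24, six organ systems each scored 0–4) is banded into
  **SOFA points** 1–4 at cut-points <6, 6–8, 9–11, ≥12.
* **Longer-term prognosis**: chronic conditions are held in a two-tier
  catalog — conditions expected to reduce 5-year survival (2 points; e.g.
  moderate dementia, NYHA class III heart failure, end-stage kidney
  disease) and conditions expected to reduce 1-year survival (4 points;
  e.g. severe dementia, metastatic cancer, cirrhosis with MELD >20).
  A patient receives a **single allotment**: 4 points if any 1-year
  condition is present, else 2 points if any 5-year condition is present,
  else 0. Points are never summed across comorbidities.

The **priority score** is the sum (1 = highest priority for resources,
8 = lowest) and is consolidated into **priority groups** 1–3. The policy
does not print the consolidation cut-points; the default used here,
scores 1–3 → group 1, 4–5 → group 2, 6–8 → group 3, is the unique
contiguous three-way split consistent with the published group-level
comorbidity distribution (no patient with a 1-year comorbidity — hence no
score ≥5 — appears in group 1, while 5-year comorbidities, reaching scores
3–4, do). It is a configuration knob (`triage_config(group_map = ...)`),
not a constant.

Ties within a group are broken by a fixed cascade: absence of a
comorbidity known to affect short-term recovery, then younger age, then
provision of an essential function within health care, then the actual
1–8 score, and finally a lottery. The policy does not enumerate the
"short-term recovery" conditions, so both that flag and the
essential-function flag are boolean inputs supplied by the caller (both
default to `FALSE` when absent). `allocate()` operationalizes the cascade
as a total order; the lottery is uniform (the policy says only "lottery")
and driven by a caller-supplied integer seed so that simulated allocations
are auditable and reproducible.

## The SOFA engine

`sofa_score()` computes the six standard subscores from daily physiology.
Conventions that the published table leaves implicit, decided here:

* **Missing components score 0** and are counted in
  `n_missing_components`. Imputing the worst case would inflate scores for
  patients with sparse charting; scoring 0 keeps totals conservative and
  matches bedside practice. Callers who want to filter on completeness
  have the count.
* Respiratory subscores 3–4 additionally require the patient to be on
  invasive or noninvasive respiratory support; a PaO2/FiO2 below 200
  without support caps at 2.
* Platelet bands use the published at-or-below thresholds
  (≤150/≤100/≤50/≤20 → 1–4), so platelets of exactly 100 score 2.
* The renal subscore is the worse of the creatinine-based and
  urine-output-based values when both are present.
* Cut-points live in an editable table (`sofa_cutpoints()`), so a SOFA
  dialect can be swapped without touching code.

A patient-day table carrying a precomputed `sofa_score` column bypasses
the engine entirely, mirroring hospitals whose electronic record
auto-calculates SOFA.

## The disparity audit

The audit asks whether the scores the algorithm assigns are associated
with race or ethnicity. Analysis is at the level of the **patient**, not
the patient-day: for each patient the maximum and the minimum of the
priority score, priority group, SOFA score and SOFA points across all
available days form eight outcomes (the extremes are what would deny —
maximum — or grant — minimum — a resource). Before aggregation,
patient-days without a SOFA score are excluded, and patients without
comorbidity data are excluded entirely, with a per-reason log.

Baseline characteristics are compared across maximum (and minimum)
priority groups with Pearson chi-squared tests (no continuity correction,
r×c tables with `Unknown` retained as a level) for categorical rows and
Kruskal–Wallis tests for continuous rows, plus a group-3-vs-1 contrast.

Each of the eight outcomes is modeled by a multivariable Poisson
regression with log link: race and ethnicity together in one model (each
adjusted for the other), plus sex, preferred language, zip-code income
band, primary insurer, age (continuous), COVID-unit admission and
hospital. Exponentiated coefficients are incidence rate ratios (IRRs)
with Wald 95% intervals. Three variants:

* **complete case** (primary): any patient with an `Unknown`/missing model
  covariate is dropped;
* **unknown category**: nobody is dropped; `Unknown` becomes an explicit
  level of every categorical covariate. Age is continuous, so the
  handful of patients with missing age are still dropped — a deliberate
  simplification over imputation, affecting ~0.3% of a realistic cohort;
* **no SES**: income band and insurer — covariates that may themselves be
  components of structural racism — are removed.

No offset is used: each patient contributes one outcome, and days of data
are a characteristic, not an exposure. Tests are two-tailed at α = .05
with no multiplicity adjustment. Tiebreaker factors are deliberately not
part of the audit.

**Standard errors.** Scores bounded in 1–8 are not Poisson counts; their
conditional variance is typically well below their mean, which makes
model-based Wald intervals conservative. Every fit therefore stores both
the model-based and the HC0 sandwich variance; `robust = TRUE` selects
which the IRR table reports. The package's simulation-calibration checks
use the robust flavor, which has asymptotically correct coverage under
the quasi-likelihood model regardless of the outcome's dispersion; the
model-based flavor is kept as the default report because it is what the
journal literature most often prints, and both are written to the audit
report for comparison.

**Reprioritization.** To quantify what including longer-term prognosis
does, each patient's full priority group is compared with the group they
would get from SOFA points alone (points 1, 2 map to groups 1, 2; points
3 and 4 are combined in group 3). The audit reports, overall and per
race/ethnicity level, the fraction of patients moved to higher priority
(strictly smaller group index), lower priority, and unchanged. The
movement can go both ways: a patient with SOFA points 2 and no
comorbidity *rises* (score 2 → group 1 beats SOFA-only group 2), while a
low-SOFA patient with a 1-year comorbidity *falls*.

## The synthetic cohort generator

No patient-level data from the motivating two-hospital cohort are
available, so `synth_cohort()` generates cohorts with the same published
statistical structure, making every pipeline stage testable end to end:

* **Marginals**: the default configuration (also `study_profile()`)
  reproduces the published cohort's n = 1127 and its race (63.1 / 28.7 /
  0.7 / 2.8 / 4.8%), ethnicity (42.6 / 54.2 / 3.2%), sex, language,
  income, insurer, hospital (59.9% tertiary) and COVID-unit (61.2%)
  distributions, and comorbidity-tier prevalences of 36.2% (5-year) and
  19.3% (1-year), drawn independently so a patient may carry both tiers.
* **Days of data**: a shifted negative binomial, `1 + NB(size = 0.7,
  mu = 4.4)`, whose parameters were fit analytically (via `qnbinom`) so
  the quartiles are exactly (2, 3, 7) — the published median 3 and IQR
  2–7. The overdispersed law is what matches a short median with a long
  right tail of ICU stays.
* **Severity**: each patient's *peak* daily SOFA score is drawn Poisson
  with log-mean `log(4.5)` plus any injected race/ethnicity effects
  (`disparity_log_irr`), truncated at 24 (a ~1e-9 event at these rates).
  Daily scores are the peak minus non-negative deviations built from an
  AR(1) latent path (ρ = 0.7, 1.5 SOFA units per latent SD), so
  trajectories are day-to-day correlated and each patient touches their
  peak at least once. This parameterization was chosen so that the
  audit's Poisson regression of the **maximum SOFA score** is *correctly
  specified*: an injected log-IRR is recoverable without attenuation,
  which is what makes parameter-recovery studies sharp. The banding into
  SOFA points and priority scores necessarily attenuates a severity
  effect — that is a property of the algorithm itself (its stated goal of
  blunting differences), not a generator artifact — so recovery is
  asserted on the unbanded outcome.
* **Missingness**: 5% of patient-days lack a SOFA score and 2% of
  patients lack comorbidity data by default — plausible magnitudes chosen
  once, since the motivating study does not print its pre-exclusion
  counts. Recovery studies set both to 0 so the observed maximum equals
  the latent peak.
* **Independence by default**: covariates are mutually independent and
  independent of severity — a *null* cohort. Two knobs break this
  deliberately: `disparity_log_irr` (severity effects) and
  `comorbidity_logit_shift` (higher comorbidity burden in a subgroup,
  the central equity concern about comorbidity-aware triage). The real
  joint distribution (income × race × insurer, etc.) is unpublished;
  the defaults are not a claim about any real population.

What passing tests on these cohorts do **not** show: robustness to
correlated covariates, to informative missingness, to miscoded race or
ethnicity, or to real physiologic dynamics. The generator emulates the
cohort's *statistical shape*, not COVID-19 disease progression.

**Randomness.** All draws flow from one caller-supplied seed through a
single stream with a fixed vectorized draw order; output is bit-identical
per seed, and the generator restores the caller's RNG state. (A
per-patient splittable-stream design was considered and rejected: base R
has no cheap splittable generator, and reseeding per patient is both slow
and statistically unhygienic.)

## Calibration studies shipped with the package

The test suite runs three simulation studies, sized to be decisive yet
quick:

* **Type-I error**: 200 null cohorts at the study profile (n = 1127,
  seeds 1–200); the Black-vs-White robust 95% CI for maximum priority
  score must exclude 1 at a rate inside the exact binomial 95% band
  around 0.05 (4–16 rejections out of 200).
* **Parameter recovery**: 100 cohorts of n = 5000 with a log-IRR of 0.2
  injected on one race level; the mean estimated IRR for maximum SOFA
  score must land within 3 Monte-Carlo standard errors of exp(0.2).
* **Marginal convergence**: one n = 50,000 cohort per check, tolerance 1%.

## Numerical and degenerate-input choices

* Chi-squared on a table with an all-zero row/column, or collapsed below
  2×2, is flagged `degenerate` with `NA` p-value rather than erroring.
* Perfectly collinear model covariates abort the fit with an error naming
  the aliased terms; a declared covariate level that is empty after
  filtering is dropped with a warning.
* A constant outcome is legal and yields IRRs of exactly 1.
* `tiebreak_compare()` is a strict weak ordering (verified exhaustively
  on an enumerated profile grid); `allocate()` resolves residual ties
  with a seeded uniform lottery and never allocates more than
  min(resources, cohort size).
* On disk, missing values are empty CSV fields; `Unknown` is an explicit
  in-memory level for categoricals. A patient with *no* comorbidities is
  written as `none` to keep "none" distinct from "not recorded".

## Known limitations

* The audit is associational; no causal or mediation claims.
* The comorbidity catalog is a fixed two-tier list; real chart review
  involves judgment the package cannot model.
* Reassessment/withdrawal over time, triage-team overrides, and
  inter-hospital coordination are out of scope.
* Poisson IRRs for bounded scores are a modeling convention inherited
  from the motivating analysis, not an optimal choice; the robust
  variance mitigates, but does not remove, the mismatch.
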