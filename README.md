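# csctriage

Crisis-standards-of-care (CSC) ventilator-triage scoring and disparity
auditing.

When a hospital must ration life-saving resources, many CSC policies rank
patients by a composite of short-term prognosis (severity of acute organ
failure) and longer-term prognosis (chronic comorbidity). A standing
concern is that comorbidity-aware scoring may systematically deprioritize
patients from racial and ethnic minority groups, who bear a higher
comorbidity burden as a consequence of structural racism. `csctriage`
implements one such institutional policy end to end, together with the
statistical audit that checks it for exactly that failure mode — for
quality-improvement teams, CSC committees, and methodologists studying
algorithmic fairness in clinical scoring.

## The algorithm and the audit

For each patient-day, the daily SOFA score (Sequential Organ Failure
Assessment; six organ systems, each 0–4, total 0–24) is banded into SOFA
points:

| SOFA score | <6 | 6–8 | 9–11 | ≥12 |
|---|---|---|---|---|
| SOFA points | 1 | 2 | 3 | 4 |

Comorbidity points come from a two-tier catalog: 2 points for any
condition expected to reduce 5-year survival, 4 points for any condition
expected to reduce 1-year survival — a single allotment for the worst
tier, never summed. The priority score is

    priority score = SOFA points + comorbidity points  ∈ {1, …, 8}

(1 = highest priority for resources), consolidated into priority groups
1–3 (default: scores 1–3 / 4–5 / 6–8). Ties within a group are broken by
short-term-recovery comorbidity, then younger age, then essential
health-care function, then the raw score, then a seeded lottery
(`allocate()` simulates the whole cascade).

The audit aggregates patient-days to per-patient maximum and minimum
outcomes, compares baseline characteristics across priority groups (χ²
and Kruskal–Wallis), and fits eight multivariable Poisson regressions —
one per outcome — of the form

    log E[score] = β₀ + race + ethnicity + sex + language
                   + income band + insurer + age + COVID unit + hospital

reporting incidence rate ratios IRR = exp(β) with Wald 95% CIs
(model-based or HC0 sandwich), with complete-case, unknown-category and
no-SES-covariate variants, plus a reprioritization table quantifying who
moves up or down when comorbidities enter the score. A synthetic
two-hospital cohort generator with injectable disparity effects makes the
whole pipeline testable without patient data.

## Worked example

```r
library(csctriage)

coh   <- synth_cohort(study_profile(), seed = 2026)  # null cohort, n = 1127
audit <- csc_audit(coh$patients, coh$patient_days)
print(audit)
```

```
CSC triage disparity audit: 1101 patients, 5856 patient-days
Exclusions:
  patient_days_missing_sofa: 275
  patients_missing_comorbidity: 19
  patient_days_of_excluded_patients: 94
  patients_with_no_retained_days: 7
Maximum priority groups: 1: 790, 2: 248, 3: 63

Primary model, maximum priority score:
Poisson disparity model (complete_case) for outcome 'max_priority_score'
  n = 937 patients (164 excluded by filtering); model-based standard errors
   covariate             level  irr          ci   p
        race             White 1.00 [Reference]
        race             Black 1.00 (0.92-1.09) .97
        race             Asian 0.73 (0.41-1.29) .28
        race       Multiracial 1.09 (0.87-1.36) .47
   ethnicity       NonHispanic 1.00 [Reference]
   ethnicity          Hispanic 0.99 (0.91-1.07) .78
   ...
```

The cohort was generated with no disparity effect, and the audit finds
none: the Black-vs-White IRR of 1.00 (0.92–1.09) says patients'
maximum priority scores are statistically indistinguishable across race
after adjustment. `audit$reprioritization_max` shows what including
comorbidities did to relative priority — here 15% of patients moved to
higher and 20% to lower priority versus SOFA-only grouping, in similar
proportions across race levels:

```
  dimension    level    n frac_higher frac_lower frac_unchanged
1   overall      all 1101        0.15       0.20           0.65
2      race    White  680        0.16       0.19           0.65
3      race    Black  334        0.15       0.18           0.67
```

A command-line pipeline is available too:

```sh
Rscript inst/cli/csctriage.R run-all --n 1127 --seed 7 --out results/demo
Rscript inst/cli/csctriage.R allocate --patients results/demo/patients.csv \
    --days results/demo/patient_days.csv --resources 10 --seed 7 --out results/alloc
```

See `vignettes/csc-triage-methods.Rmd` for the model, its assumptions,
every tunable parameter, and what the synthetic cohorts do and do not
emulate.

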