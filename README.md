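# bnhlphenotype

Computable phenotyping of de novo pediatric mature B-cell non-Hodgkin
lymphoma (B-NHL) in hospital administrative claims.

Pediatric B-NHL (Burkitt lymphoma, diffuse large B-cell lymphoma and
related entities) is rare enough that large-scale epidemiologic and
comparative-effectiveness work depends on administrative databases — but
ICD diagnosis codes alone identify newly diagnosed pediatric cancer
patients poorly. This package implements a two-step computable phenotype
that recovers a high-confidence de novo B-NHL cohort from four ordinary
claims tables (demographics, admissions, per-admission diagnosis codes,
dated pharmacy billing lines):

1. **Code screen + billing filter.** Patients are flagged if any
   admission carries a diagnosis code matching the B-NHL screening list
   by prefix (ICD-9 `200.0x`, `200.2x`, `200.5x`, `200.7x`, `200.8x`,
   `202.8x`, `202.9x`, or the ICD-10 analogues `C83.3x`–`C96.Z`), then
   excluded if they lack billing for *all* of the pre-specified
   chemotherapy screen agents.
2. **Chemotherapy-regimen review.** Each screened patient's dated drug
   bills, over a 45-day review window from the index admission, are
   segmented into candidate cycles and fuzzily matched against standard
   B-NHL cycle templates — COP, COPADM, R-COPADM, COPAD, R-EPOCH, and
   BFM-95 courses 1–2 — under explicit tolerance rules: intra-cycle
   schedule shifts of at most ±2 days, at most one absent drug class per
   cycle, and any number of additional steroid days. A patient enters
   the cohort if a qualifying multi-cycle pattern is found (e.g. a
   COPADM/R-COPADM plus a preceding COP or a second COPADM/R-COPADM; two
   COPADs; two R-EPOCHs; BFM-95 course 1 then course 2), if a lone COP
   is followed by no inpatient encounter for 45 days, or if a 60-day
   lookback before the index admission completes a qualifying sequence.

Validation statistics come with the package: sensitivity `TP/(TP+FN)`
and positive predictive value `TP/(TP+FP)` with Clopper–Pearson exact
binomial confidence intervals, Pearson chi-square demographic
comparisons against a cancer-registry reference, and Cohen's kappa
`(p_o − p_e)/(1 − p_e)` for inter-rater agreement. Because real
pediatric claims are proprietary, a seeded synthetic claims generator
(`simulate_claims()`) produces labelled cohorts with the false-positive
and false-negative mechanisms that code-based screening actually
exhibits (miscoded alternate diagnoses, relapsed disease, late-course
transfers-in, coding without malignancy; missing codes and altered
regimens), so every stage of the pipeline is testable end to end.

## Worked example

```r
library(bnhlphenotype)

sim <- simulate_claims(cohort_spec(n_patients = 200, seed = 7))
fit <- bnhl_phenotype(sim$claims)
summary(fit)
#> Two-step B-NHL computable phenotype
#>
#> Stage funnel:
#>   screened patients         200
#>   passed code screen        195
#>   passed billing filter     191
#>   included in cohort        110
#>
#> Inclusion rules fired:
#>   BFM95_SEQUENCE           18
#>   COP_ONLY_NO_RETURN        6
#>   REPOCH_PAIR              18
#>   TWO_COPAD                 1
#>   TWO_CYCLE_STANDARD       67
#>
#> Tolerances: max shift 2 d, max missing classes 1, review 45 d, lookback 60 d

tab <- build_table(fit, sim$gold)
sensitivity(tab)
#> sensitivity: 92.0% (95% CI 85.3-96.3%) [103/112]
ppv(tab)
#> ppv: 93.6% (95% CI 87.3-97.4%) [103/110]
```

The funnel counts show how many of the 200 simulated patients carried a
qualifying diagnosis code, how many also had chemotherapy billing, and
how many survived regimen review. Against the generator's gold labels,
the phenotype captured 103 of 112 true B-NHL patients (92.0%
sensitivity; the 9 misses are planted false negatives — patients without
a screening code or with regimens altered beyond tolerance), and 103 of
the 110 included patients were true cases (93.6% PPV; the false
positives are relapsed or miscoded patients treated on full B-NHL
regimens, whom billing data cannot distinguish from de novo disease).

Published single-centre validation counts ship with the package:

```r
vc <- validation_counts()
ppv(vc$full_pipeline)
#> ppv: 95.1% (95% CI 88.9-98.4%) [97/102]
demographic_comparison("race")
#> Pearson chi-square: X2 = 4.855, df = 1, p = 0.02763
```

A full run (read or simulate claims → screen → match → validate →
`cohort.csv` + `report.json`) is one call: `run_pipeline()`, or the thin
command-line wrapper in `inst/scripts/bnhl-phenotype.R`.

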