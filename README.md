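# hopeval

Survival prognostication for accidental hypothermia with cardiac arrest,
and the machinery to validate it honestly.

The HOPE score (Hypothermia Outcome Prediction after ECLS) estimates the
probability that a hypothermic cardiac-arrest patient will survive to
hospital discharge after extracorporeal rewarming, from six covariates
available at admission: age, sex, mechanism of hypothermia, core
temperature, serum potassium, and CPR duration (CPR start to ECLS start).
The model is a fixed logistic score:

```
score = 2.44 − 1.55·male − 1.95·asphyxia − 0.0191·age
        − 2.07·log2(K) − 0.573·log2(CPR) + 0.937·T − 0.0247·T²

P(survival) = exp(score) / (1 + exp(score))
```

with potassium K in mmol/L, CPR in minutes, temperature T in °C, and
`asphyxia = 1` for airway-compromising mechanisms (submersion; avalanche
with the head buried). A survival probability ≥ 10% is the suggested
criterion to initiate ECLS rewarming.

`hopeval` is aimed at clinical-prediction researchers and at anyone
re-validating the score on their own extraction of cases. It provides:

* **Scoring** — `hope_score()` on a cohort table, with strict input
  validation, out-of-range and pediatric flags, and the explicit
  `+30 min` admission-to-ECLS imputation (`add_30min_ids`).
* **Triage diagnostics** — `confusion_table()`, `diagnostic_report()`
  (sensitivity, specificity, PPV, NPV, FP/FN fractions, all with Wilson
  intervals), `roc_auc()` (Mann–Whitney AUC, DeLong CI).
* **Calibration** — `calibration_summary()` (calibration-in-the-large:
  mean predicted vs observed survival, group means, rank-test comparison,
  bootstrap interval for the gap), `asphyxia_sensitivity()` /
  `shift_asphyxia()` for the uncertain immersion-vs-submersion scenario.
* **Synthetic cohorts** — `cohort_config()` + `sample_cohort()` +
  `simulate_outcomes()` + `apply_publication_bias()`: a generator anchored
  to published cohort marginals, a model-faithful outcome simulator, and an
  outcome-dependent retention filter that reproduces how publication bias
  inflates observed survival in case-report samples while leaving
  discrimination intact.
* **IO and summaries** — `read_cohort()` / `write_cohort()` (delimited
  text, canonical columns), `summarize_cohort()` (study-table descriptives
  with Fisher / Mann–Whitney group comparisons), `hope_fixtures()`.

Results are tibbles or small S3 objects with `tidy()` / `glance()` /
`autoplot()` methods, so everything chains with the pipe.

## Worked example

Score the published pediatric false-negative case — a 6-year-old boy,
submerged, 17 °C, potassium 7.6 mmol/L, ECLS after 95 min of CPR, who
survived fully:

```r
library(hopeval)

boy <- hope_fixtures()$pediatric_case
hope_score(boy)[, c("hope_score", "hope_probability")]
#> # A tibble: 1 × 2
#>   hope_score hope_probability
#>        <dbl>            <dbl>
#> 1      -2.21           0.0993
```

A predicted survival of 9.93% sits just below the 10% rewarming threshold
(the rule compares unrounded values), which is exactly why this survivor is
the single false negative of the validation cohort. The row's
`hope_warnings` also flags him as pediatric, where guidelines recommend
expert consultation over the score.

The eight published non-survivor probabilities, run through the 10% rule:

```r
dead <- tibble::tibble(
  hope_probability = hope_fixtures()$non_survivor_probabilities,
  outcome = "died"
)
confusion_table(dead, threshold = 0.10)
#> Confusion table at threshold 10% (positive = rewarm)
#>   tp=0 fp=5 tn=3 fn=0  (n=8 known outcomes, 0 missing)

diagnostic_report(confusion_from_counts(tp = 61, fp = 5, tn = 3, fn = 1))
#> Diagnostic performance at HOPE probability >= 10% (95% CI, Wilson)
#>   sensitivity  61/62 = 98% (91%-100%)
#>   specificity  3/8 = 38% (14%-69%)
#>   ppv          61/66 = 92% (83%-97%)
#>   npv          3/4 = 75% (30%-95%)
#>   fp_fraction  5/70 = 7% (3%-16%)
#>   fn_fraction  1/70 = 1% (0%-8%)
```

Three of eight non-survivors fall below 10% (specificity 38%); the five
above it are futile-rewarming false positives — 7% of the cohort.

The publication-bias mechanism, end to end: simulate a consecutive-series
cohort (base survival ≈ 40%), keep survivors with probability 0.9 and
non-survivors with probability 0.05 (case-report selection), and compare:

```r
cfg    <- cohort_config(n = 20000, seed = 42, profile = "consecutive")
cohort <- sample_cohort(cfg) |> hope_score()
full   <- simulate_outcomes(cohort, "model_faithful", seed = 42)
kept   <- apply_publication_bias(full, retention_survivor = 0.9,
                                 retention_non_survivor = 0.05, seed = 42)

glance(roc_auc(full))$auc   # 0.861
glance(roc_auc(kept))$auc   # 0.860  — discrimination untouched

calibration_summary(kept, boot_n = 0)
#> Calibration-in-the-large (n = 8012 with known outcome)
#>   mean predicted survival  61%
#>   observed survival        93%
#>   gap (observed - mean predicted)  +0.316
#>   ...
```

Retention that depends only on the outcome cannot reorder predictions
within a class, so the AUC is preserved; but the observed survival rate is
pushed from 41% to 93% — matching the closed form
`r_s·s / (r_s·s + r_n·(1−s)) = 0.927` — while the mean prediction moves far
less. This is the dissociation seen when a consecutive-cohort score is
evaluated on case reports: good discrimination, broken calibration, and an
inflated positive predictive value.

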