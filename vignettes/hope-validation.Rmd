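---
title: "Validating a survival score for hypothermic cardiac arrest: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a survival score for hypothermic cardiac arrest: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hopeval)
```

## The model

Accidental hypothermia can make cardiac arrest survivable for far longer
than normothermia, and extracorporeal life support (ECLS) rewarming gives
these patients a real chance of neurologically intact survival. The HOPE
score summarises that chance as a logistic model over six covariates
available at hospital admission:

$$\mathrm{score} = 2.44 - 1.55\,\mathrm{male} - 1.95\,\mathrm{asphyxia}
  - 0.0191\,\mathrm{age} - 2.07\log_2 K - 0.573\log_2 \mathrm{CPR}
  + 0.937\,T - 0.0247\,T^2,$$

$$P(\text{survival}) = \frac{e^{\mathrm{score}}}{1 + e^{\mathrm{score}}},$$

with age in years, serum potassium $K$ in mmol/L, CPR duration (CPR start
to ECLS start) in minutes and core temperature $T$ in °C. Both logarithms
are base 2; `hopeval` evaluates them through R's native `log2()`, which
agrees with $\ln x / \ln 2$ to below $10^{-12}$ across the clinical range.
The coefficients are fixed constants of the published model: this package
validates the score, it never refits it, and `hope_coefficients()` flags
any user override in the scoring metadata.

Structural consequences worth knowing:

* Survival probability is strictly decreasing in potassium, CPR duration,
  age, male sex and the asphyxia flag.
* The temperature term is a concave quadratic on the log-odds scale with
  vertex at $0.937 / (2 \times 0.0247) \approx 18.97\,$°C: colder is
  protective only down to about 19 °C.
* The asphyxia flag shifts the log-odds by exactly 1.95, and sex by 1.55,
  regardless of the other covariates. The asphyxia shift is clinically
  large — a 16% (submersion) patient becomes 57% under immersion — which
  is why `asphyxia_sensitivity()` computes both scenarios and labels the
  non-asphyxial one as the when-in-doubt choice.

## Data-preparation conventions

**Mechanism classification.** Submersion and avalanche burial of the head
compromise the airway and count as asphyxial; outdoor/indoor cold exposure
and immersion (head above water) do not. `classify_mechanism()` encodes
this vocabulary; an `asphyxia` column may also be supplied directly, but
if both are present they must agree, and a contradiction is a per-record
error.

**CPR imputation.** Reports sometimes give CPR duration only up to
hospital admission. The convention is to add 30 minutes for the
admission-to-ECLS interval. This is opt-in and per record
(`add_30min_ids` in `hope_score()`, or `impute_cpr_from_admission()`),
and the imputed rows carry a provenance flag — the adjustment is never
applied silently.

**Exclusions are the pipeline's job, not the formula's.** The score is a
total function of any positive potassium and CPR duration, so
`hope_score()` warns rather than fails for covariates outside the ranges
observed in validation cohorts (age 1–95 y, temperature 13.5–28.9 °C,
potassium 2.4–16.1 mmol/L, CPR 20–307 min), for temperatures above 32 °C
(at which arrest is unlikely to be hypothermia-induced, a study-level
exclusion criterion), and for pediatric ages (< 18 y), where guidelines
recommend expert consultation rather than the score. Missing covariates,
by contrast, make a record unscorable: in the default fail-soft batch mode
the row gets `NA` with the reason recorded, and `on_invalid = "error"`
turns the first problem into a rejection naming the field.

## Thresholding and diagnostics

The decision rule "rewarm if predicted survival ≥ 10%" is inclusive and is
applied to **unrounded** probabilities. This matters at the boundary: the
known pediatric false-negative case scores 9.928%, which displays as 9.9%
or 10% depending on rounding but is below the threshold either way the
rule is stated. Display rounding in reports is half away from zero
(`format_percent()`: 37.5% prints as 38%), one decimal by default for
probabilities and integer percent in the diagnostic table; full precision
is kept internally and on disk. One display discrepancy is documented
rather than modelled: the 9.928% case has circulated printed as "9.92%",
which is a truncated rather than rounded two-decimal display; `hopeval`
rounds (9.93%) and does not attempt to reproduce the truncating
convention.

`diagnostic_report()` computes sensitivity (criterion fulfilled among
survivors), specificity (criterion not fulfilled among non-survivors),
PPV, NPV, and false-positive/false-negative fractions over all patients,
each with a Wilson score interval. The Wilson interval is used everywhere
a proportion is reported: it is well-behaved at the tiny denominators this
field produces (an NPV of 3/4 is a realistic cell). A zero denominator
yields an explicit "undefined" entry, never a silent zero. The Wilson
implementation is the closed form, cross-checked in the test suite against
the score-test inversion in `stats::prop.test(correct = FALSE)` and
against its exact enumerated coverage.

`roc_auc()` reports the Mann–Whitney concordance AUC with a DeLong
interval (the conventional default, via pROC). When an outcome class has a
single member the DeLong variance degenerates, and the interval falls back
to a seeded outcome-stratified bootstrap (2,000 resamples by default),
labelled as such in the output. The ROC curve is constructed from every
distinct predicted value under the same inclusive rule, and the trapezoid
area under it equals the reported AUC to $10^{-10}$ — an invariant the
tests enforce.

## Calibration

Calibration-in-the-large — mean predicted survival versus observed
survival — is the primary calibration measure, because it is the one that
selection bias destroys first and the one that matters for triage: a score
can rank patients perfectly and still promise 54% survival where 89%
survive. `calibration_summary()` reports the gap (observed − mean
predicted) with a seeded nonparametric bootstrap interval; no specific
parametric test is attributed to the predicted-vs-observed comparison,
since none is canonical. The survivor/non-survivor location difference in
predictions is tested with a two-sided Mann–Whitney test (continuity
corrected, normal approximation). Logistic recalibration (intercept and
slope of `outcome ~ logit(p)`) is available behind `recalibrate = TRUE`
as a labelled extension, off by default.

## The synthetic-cohort generator

No individual-level data ship with this package, so every pipeline stage
is exercised against synthetic cohorts from `cohort_config()` +
`sample_cohort()`. The default (`profile = "case_reports"`) reproduces the
marginal covariate structure of a published 70-patient case-report cohort:
67% male; mechanism weights 0.59 exposure, 0.13 immersion, 0.21
submersion, 0.07 avalanche; and continuous covariates from truncated
families anchored to the published medians and full ranges:

| covariate | family | parameters | support | target median |
|---|---|---|---|---|
| age (y) | mixture of truncated normals | 0.30·N(8, 5) on [1, 17] + 0.70·N(40, 22) on [18, 95] | [1, 95] | 33 |
| temperature (°C) | truncated normal | N(22.7, 3.5) | [13.5, 28.9] | 22.7 |
| potassium (mmol/L) | truncated lognormal | meanlog log 4.2, sdlog 0.35 | [2.4, 16.1] | 4.2 |
| CPR (min) | truncated lognormal | meanlog log 95, sdlog 0.55 | [20, 307] | 95 |

Right-skewed families were chosen because the published medians sit well
below the range midpoints; the child/adult age mixture reflects the
substantial pediatric fraction implied by a range starting at 1 year. Only
medians and ranges constrain these choices — the spread between them is
otherwise unconstrained by the source material, and all parameters are
user-overridable through the `dist_*()` descriptors.

The `"consecutive"` profile keeps the same families with a graver casemix
(30% submersion, 10% avalanche, potassium median 5.0 mmol/L, CPR median
120 min) so that model-faithful outcomes give a base survival near 40%,
comparable to consecutive-series cohorts. It is the natural base
population for bias experiments: consecutive series are what the score was
derived on, and case-report samples are what selection bias produces from
them.

**What the generator does not emulate.** Covariates are sampled
independently; real cohorts correlate mechanism with potassium and
temperature with CPR duration, among others, and no joint distribution is
available to calibrate against. Passing tests therefore demonstrate the
pipeline's correctness and the selection-bias mechanism, not distributional
fidelity to any real joint casemix. pH, lactate, rhythm and witnessed
status are not generated at all.

**Outcomes and bias.** `simulate_outcomes(mode = "model_faithful")` draws
outcome ~ Bernoulli(HOPE probability) — the null hypothesis under which
the score is perfectly calibrated, matching how the score behaves on
consecutive validation samples. `mode = "fixed_rate"` draws at a flat rate
regardless of covariates. `apply_publication_bias()` retains each record
independently with a probability depending only on its outcome class; it
alters membership and nothing else, which is the formal reason
discrimination survives (within-class prediction ranks are untouched)
while the retained survival rate moves to
$r_s s / (r_s s + r_n(1-s))$ — available in closed form as
`retained_survival_rate()` and verified by simulation in the tests.

**Randomness.** All three operations derive per-record substream seeds
from one master seed by a counter-based linear mix (modulo $2^{31}-1$)
with a distinct stage constant per operation. Consequences: identical
seeds give identical cohorts element-wise; the first $k$ records of a
size-$n$ cohort equal the size-$k$ cohort; and outcome draws are
independent of covariate draws under the same seed.

## Problem sizes and numerical tolerances

The test suite exercises exact identities (logit shifts, batch/pointwise
equality, AUC vs a brute-force pairwise oracle on cohorts of ≤ 30) at
tolerances of $10^{-10}$–$10^{-12}$, and stochastic properties at sizes
chosen so Monte-Carlo error is small relative to the asserted bounds:
median targets at n = 10,000 (within 10%), model-faithful calibration at
n = 5,000 (within 2 binomial standard errors), and the bias dissociation
at n = 20,000 with retention 0.9/0.05 (gap > 0.2; AUC preserved within
3 concordance standard errors). Property suites over randomized records
use 1,000 cases under fixed seeds.

## Known limitations

* The score itself is taken as given; nothing here assesses its derivation
  or refits it, and the package deliberately provides no survival
  modelling beyond in-hospital discharge.
* The negative-predictive-value side of any validation is fragile whenever
  non-survivors are scarce — intervals like 30–95% on 3/4 are the honest
  width, not a defect of the method.
* The generator's independence assumption (above) limits what synthetic
  experiments can say about covariate-conditional behaviour on real data.
* Pediatric patients are scored but flagged; the score is not recommended
  as the basis for rewarming decisions in children.
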