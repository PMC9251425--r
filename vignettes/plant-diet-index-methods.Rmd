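---
title: "Methods: plant-based diet indices and wave-observed cohort analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plant-based diet indices and wave-observed cohort analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdicohort)
```

This vignette is the package's own account of its methods: the scoring
model and its assumptions, the parameters that matter, what the synthetic
cohort generator does and does not emulate, and the numerical and design
choices made where more than one defensible option existed.

## 1. From recalls to an exposure

The exposure is a quintile-based dietary pattern score built from
repeated 24-hour recalls.

**Aggregation.** Each participant contributes up to three recall days per
baseline survey year (2004, 2006) and up to both years. Intakes are the
arithmetic mean over available days — a group reported on no day is zero
intake, not missing — then averaged element-wise across the two baseline
years; single-year participants keep that year's values, and the earliest
year present becomes the baseline year that anchors follow-up time.
Aggregation is linear in grams and permutation-invariant over days.

**Energy filter.** Profiles with total energy below 500 or above
5,000 kcal/day are excluded as implausible. The bounds are written as
strict inequalities, so the boundary values themselves are retained; the
filter is idempotent and its bounds are arguments of `filter_energy()`.

**Residual-method energy adjustment.** Each group's intake is regressed
on total energy by ordinary least squares across the analysis sample, and
the adjusted intake is the residual plus the predicted intake at the
sample-mean energy. This classic form keeps g/day units and preserves the
sample mean; adding a constant to every energy leaves adjusted intakes
unchanged, and rescaling intakes by *c* rescales them by *c*. Two
defensible variants exist — log-transforming intakes before regression,
and adjusting within strata — and the untransformed whole-sample OLS is
the default because nothing in the source material indicates otherwise.
With zero energy variance the regression is degenerate; the function then
returns raw intakes with a classed warning rather than failing, which is
also what the extreme-fixture constructions rely on.

**Quintiles with midranks.** Ranks use midranks for ties, the fractional
rank is (rank − ½)/n, and the quintile is ⌊5f⌋ + 1 (clamped to 5). The
tie rule matters: tea/coffee, sugary drinks, dairy and nuts are
zero-inflated, and naive quantile cut-points would either collapse or
split the tied mass across quintiles nondeterministically. Midranks make
the assignment deterministic, order-independent, and guarantee equal
values share a quintile — at the cost that heavily tied groups can leave
some quintile labels unoccupied, which propagates honestly into absent
quintile rows in stratified tables.

**Scoring and summation.** Positive direction: score = quintile; negative:
score = 6 − quintile. PDI scores all 12 plant groups positively, 5 animal
groups negatively; hPDI scores the 7 healthy plant groups positively and
the other 10 negatively. Totals over 17 groups lie in [17, 85]; flipping
every direction maps a total *t* to 102 − *t*, a mirror property the test
suite checks exactly.

**The 17th group.** The source classification enumerates 7 healthy plant,
5 less-healthy plant and 5 animal groups — exactly 17 — while also
describing a fermented-foods category added for the Chinese food supply.
Treating fermented foods as an 18th group would contradict both the
stated group count and the 17–85 range, so the default map carries a
single `fermented_preserved` group (preserved *and* fermented foods)
categorized as less-healthy plant, where preserved foods are listed.
Whether fermented foods deserve healthy-plant status is genuinely open;
the category is a column of the map, and `food_group_map()` accepts any
17-group re-categorization.

**Quintile frame.** Per-group quintiles and the exposure quintiles of the
total are computed within each per-outcome analysis sample (the default),
since scoring is described inside the analytic cohort; cut-points frozen
on the whole energy-filtered cohort are available via
`quintile_within = "cohort"` in `build_analysis_sample()`.

## 2. Outcomes, exclusions, follow-up

Outcomes are ascertained from wave measurements: overweight/obesity is
BMI ≥ 24 kg/m² (the combined endpoint of the Chinese Working Group
threshold; no separate ≥ 28 obesity subclass), hypertension is
SBP ≥ 140 mmHg or DBP ≥ 90 mmHg or self-report/medication, and type 2
diabetes is wave-specific: at the biomarker wave (2009) fasting glucose
≥ 7.0 mmol/L, HbA1c ≥ 6.5% or self-report/medication; at 2015,
self-report/medication only, with biomarkers ignored even if present.

The exclusion flow runs in a fixed order — energy filter, prevalent
cardiovascular disease/cancer, loss to follow-up, prevalent outcome,
missing outcome — and the ledger attached to every `analysis_sample`
satisfies excluded + retained = input by construction, a conservation law
the tests assert for every outcome on every synthetic cohort.

**Event timing.** An event is assigned to the first attended wave whose
measurements satisfy the outcome definition, and follow-up is (event or
censoring wave) − baseline year. Assigning the wave year rather than an
interval midpoint keeps the analysis convention aligned with what is
observable in wave data and keeps person-years integral; it also means
event times are heavily tied, which drives the choice of the Efron tie
correction below. A side simulation (continuous versus wave-grouped
observation of the same latent times) puts the attenuation cost of this
convention below 3% of the log hazard ratio at the event rates used here,
well inside the Monte-Carlo spread of the recovery checks. Participants
diagnosed between waves are necessarily detected at the next attended
wave; no left-truncation or interval-censoring model is applied.

## 3. Survival models

`fit_cox()` maximizes the Cox partial likelihood (via the `survival`
package) on the follow-up-years time scale with Wald intervals. Efron's
tie correction is the default because wave-year event times produce large
tie groups; Breslow is available through the model spec. Covariates enter
as an explicit numeric design matrix (education as three indicator
contrasts), constants are dropped with a classed warning, and
coefficients driven to ±∞ by monotone likelihood are flagged
non-estimable rather than reported as numbers.

The three covariate sets are nested: model 1 {urban/rural, age, sex,
total energy}; model 2 adds {education, physical activity (MET/day),
smoking, alcohol}; model 3 adds {BMI}, plus baseline SBP/DBP for the
spline and ROC runs.

**Trend.** Each participant's exposure is replaced by their quintile's
median index total, entered continuously; the Wald p of that coefficient
is the p-trend. No multiple-testing correction is applied anywhere.

**Per SD.** The index z-score uses the analysis-sample SD. The identity
HR/SD = exp(β_raw · SD) is kept as an exact cross-check in the tests.

**Splines.** The restricted cubic spline uses Harrell's truncated-power
basis with 4 knots at the 5th/35th/65th/95th percentiles — the standard
compromise between flexibility and stability when neither knot count nor
placement is prescribed — referenced at the sample median, where the HR
is exactly 1 by construction. The basis spans the same space as
`splines::ns` with matching knots (asserted in the tests via equal
maximized partial likelihoods); the hand-written form is kept because the
curve needs explicit contrasts against an arbitrary reference value.

**Proportional hazards.** Each term is augmented with a term × log(t)
interaction (`survival`'s `tt` mechanism); the Wald p per interaction
flags violations. Log time is the conventional scaling and is
well-defined here since follow-up is at least 3 years.

**Stratification.** Sex and age (<55 / ≥55 years) strata re-run the
quintile model and trend test with exposure categories *fixed from the
parent sample*, so "Q5" means the same diet in both strata;
recomputing quintiles within the stratum is available by rebuilding the
sample on the subset. Strata with fewer than 2 events are skipped with a
warning rather than fitted.

## 4. Discrimination and description

ROC analysis is static: the label is event versus no event over the whole
follow-up, matching a design that reports a single AUC per outcome;
censoring before the first event wave counts as no event, exactly as the
sample defines it. Whether such AUCs should come from logistic models or
Cox linear predictors is not specified anywhere authoritative; the
default risk score is the linear predictor of the fully adjusted Cox
model (model 3 + baseline blood pressure) including the index term, which
uses the same estimand as the hazard analyses. AUCs use the rank
statistic with ties counted half; intervals and the paired comparison use
DeLong's structural components (via `pROC`), with the degenerate
identical-model comparison short-circuited to Δ = 0, p = 1. Descriptive
tables use ANOVA for continuous variables (Kruskal–Wallis on request via
`nonnormal=`, a deliberate flag rather than automatic normality testing,
which would make table contents data-dependent), and uncorrected
chi-square for categorical ones.

## 5. The synthetic cohort generator

The generator exists so that every downstream stage has a testable ground
truth. It emulates, per participant: baseline covariates with realistic
marginals (age ~46 ± 13 truncated to 18–80, 48% male, 72% rural, four
education strata, log-normal MET/day, 33%/34% smoking/alcohol, 1.4%
prevalent CVD/cancer); three recall days per attended baseline year
across the 17 groups with participant-level zero inflation (non-consumers
of tea/coffee, dairy, sugary drinks are common), log-normal consumer
amounts shifted by a latent diet-quality factor (inducing the positive
within-plant and negative plant–animal intake correlations seen in real
recalls), day-to-day log-normal noise, and reported energy equal to an
intercept plus energy-density-weighted intakes plus noise (mean ≈ 2,230
kcal/day); wave attendance with a 26.6% loss-to-follow-up rate (a 73.4%
follow-up rate), 90% per-wave attendance and 5% block-wise measurement
missingness; and baseline prevalences of 44.4%/43.3%/3.8% for the three
outcomes.

**Ground truth and the scoring path.** Latent event times are exponential
(Weibull with `weibull_shape` ≠ 1 for deliberate PH violations) with log
hazard β·z + 0.02·(age − 45) + 0.1·male on per-outcome baseline hazards
(0.035, 0.032, 0.009 per year), where **z is the standardized PDI
computed from the generated recalls through the package's own scoring
path**, not an independent latent variable. This choice is what makes
parameter recovery a meaningful end-to-end test: the analysis recomputes
the index from observable tables (never from the retained truth table),
and any scoring discrepancy would surface as attenuation. The default β
are the fully adjusted per-SD hazard ratios 0.89/0.88/0.93. Outcomes are
observed only at attended waves: measurements first satisfy a definition
at the first wave at or after the latent event time and stay below
thresholds before it; biomarkers exist only at 2009, while carried
self-report keeps 2015 diabetes ascertainment possible.

**What it does not emulate.** Item-level foods (generation is at group
level), household food weighing, multi-stage geographic sampling, secular
dietary trends between baseline years, informative missingness (all
attendance and missingness is independent of diet and outcome), and
energy misreporting. Consequently a passing recovery test demonstrates
that the pipeline is internally consistent and well calibrated under
clean interval observation — not that the index is unconfounded in real
data, where diet correlates with attendance, reporting quality and
unmeasured behavior. The energy filter almost never triggers on generated
data (reported energies rarely leave [500, 5000]); its boundary behavior
is therefore pinned by explicit fixtures instead.

**Determinism.** Every generator stage derives its own sub-seed
deterministically from `sim_config(seed=)`, so identical configs yield
byte-identical datasets, and `write_dataset()` prints doubles at 17
significant digits so the CSV round trip is exact; the manifest records
the seed and a config hash.

## 6. Problem sizes and tolerances

The analysis scripts use 3,000 participants (seed 2004) — large enough
for stable quintile HRs at the generated event rates, small enough to run
the whole workflow in seconds. The recovery checks use 20 replicates of
5,000 participants (CI coverage of a true HR 0.85/SD in ≥ 18, null
rejections ≤ 2) and the calibration check 200 replicates of 700
participants (trend-test size within a ±3 SD binomial band around 5%;
spline reference HR exactly 1 in every run). Exact oracles are asserted
tightly: the closed-form residual-adjustment example exactly, the
3-subject Cox fixture against grid-search maximization of the
hand-written partial likelihood to 1e-4 (the two implementations agree to
1e-6), AUC against exhaustive pair counting exactly.

## 7. Known limitations

- Interval observation is analyzed with wave-year event times, not an
  interval-censored likelihood; the induced attenuation is small at these
  event rates but grows with sparser waves or higher hazards.
- The trend test inherits the usual caveat that quintile medians are
  sample statistics; their sampling variability is ignored, as is
  conventional.
- DeLong comparison of two nested Cox linear predictors evaluated on
  their training sample is optimistic about both AUCs; only the
  *difference* between the two index models is interpreted.
- The uPDI (unhealthful index) of the original scoring framework is out
  of scope, as are competing risks, frailty, time-varying diet exposure,
  nutrient-level computation and calibration/reclassification metrics.
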