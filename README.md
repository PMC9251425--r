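# pdicohort

Plant-based diet indices and cardiometabolic outcomes in longitudinal
cohorts: index construction, exclusion-flow sample building, Cox
proportional-hazards analyses, spline dose–response, discrimination
comparison — plus a seeded synthetic cohort generator with known ground
truth so every stage is testable without access to restricted survey
microdata.

## The problem

Nutritional epidemiology increasingly scores *how plant-based* a diet is
rather than whether someone is vegetarian. The overall plant-based diet
index (PDI) and the healthful plant-based diet index (hPDI) summarize
repeated 24-hour dietary recalls into a single graded exposure, which is
then related to incident overweight/obesity (BMI ≥ 24 kg/m²),
hypertension (SBP ≥ 140 mmHg, DBP ≥ 90 mmHg, or self-report/medication)
and type 2 diabetes (fasting glucose ≥ 7.0 mmol/L, HbA1c ≥ 6.5%, or
self-report, with wave-specific ascertainment rules) over a decade of
wave-based follow-up.

## The index

Foods are classified into **17 food groups**: 7 healthy plant (whole
grains, fruits, vegetables, nuts, legumes, tea and coffee, vegetable
oils), 5 less-healthy plant (refined grains, potatoes, sugary drinks,
sweets and desserts, preserved/fermented foods), and 5 animal (animal
fats, dairy, eggs, fish or seafood, meat). For each group *g* with intake
*x<sub>ig</sub>* (g/day, the mean of three 24-h recalls averaged over the
two baseline years):

1. **Energy adjustment (residual method).** Regress *x<sub>g</sub>* on
   total energy *E* across the sample; the adjusted intake is the residual
   plus the predicted intake at the sample-mean energy, keeping the
   original units and mean.
2. **Quintile ranking.** Midrank-based quintiles
   *q* = ⌊5 (rank − ½)/n⌋ + 1, so tied intakes (ubiquitous in
   zero-inflated groups) never straddle a quintile.
3. **Directional scoring.** Positive direction: score = *q* (fifth
   quintile scores 5); negative: score = 6 − *q* (fifth quintile scores
   1). PDI scores all plant groups positively and animal groups
   negatively; hPDI scores only healthy plant groups positively.
4. **Summation.** The 17 group scores sum to the index, theoretical range
   **17–85**; the total is itself divided into quintiles for analysis.

Association is estimated with Cox proportional-hazards models on the
follow-up-years time scale (Efron ties — event times sit on wave years):
model 1 adjusts for urban/rural, age, sex, total energy; model 2 adds
education, physical activity, smoking, alcohol; model 3 adds BMI. Linear
trend is tested by entering each quintile's median index score as a
continuous covariate; continuous effects are reported per 1 SD; the
fully adjusted dose–response is a restricted cubic spline (4 knots at the
5th/35th/65th/95th percentiles); and PDI- vs hPDI-based prediction models
are compared by AUC with the paired DeLong test.

## Worked example

The `analysis/` scripts form the complete workflow; each is a thin driver
over exported functions and writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # synthetic cohort -> results/dataset
Rscript analysis/02_score_index.R     # PDI / hPDI scores
Rscript analysis/03_build_samples.R   # exclusion flow per outcome
Rscript analysis/04_survival_models.R # Cox models, trend, splines, strata
Rscript analysis/05_discrimination.R  # ROC comparison
```

With the default configuration (3,000 participants, seed 2004) the run
prints, among others:

```
PDI : range 23-72, mean 51.0, sd 6.61; quintile medians 42/48/52/55/59
hypertension      : retained 1258 of 3000; events 369 (29.3%); person-years 11552
hypertension       PDI : Q5 vs Q1 HR 0.65 (0.46-0.91), p-trend 0.0411, HR/SD 0.86 (0.77-0.96)
hypertension      : AUC PDI 0.622 (0.589-0.656) vs hPDI 0.623 (0.589-0.657), p = 0.933
```

Reading: index totals stay inside the theoretical 17–85 band with an SD
close to 6 points; after the exclusion flow (energy filter, prevalent
cardiovascular disease/cancer, loss to follow-up, prevalent hypertension,
missing outcome) 1,258 participants contribute 11,552 person-years; the
highest PDI quintile has a 35% lower hypertension hazard than the lowest,
with a significant linear trend and an HR of 0.86 per SD — consistent
with the generator's built-in true effect (HR 0.88/SD) — and the two
indices discriminate equally well (DeLong p = 0.93).

Because the cohort is synthetic with known ground truth, the test suite
closes the loop: with a true HR of 0.85 per SD injected, the pipeline's
95% CI covers the truth in ≥ 18 of 20 seeded replicates, and under a null
effect the trend test rejects at its nominal 5% rate.

## Layout

- `R/` — the package: generator (`sim_config`, `simulate_cohort`), intake
  processing (`build_profiles`, `filter_energy`), scoring
  (`compute_index`, `index_quintiles`), ascertainment and exclusion flow
  (`ascertain_outcomes`, `build_analysis_sample`), survival models
  (`fit_cox`, `trend_test`, `hr_per_sd`, `fit_rcs`, `test_ph`,
  `stratified_analysis`), evaluation (`compute_auc`, `compare_auc`,
  `descriptive_table`).
- `vignettes/` — methods vignette: model, assumptions, parameter choices,
  limitations.
- `inst/extdata/food_groups.yaml` — the 17-group classification with an
  item-code lookup stub.
- `tests/testthat/` — unit, property and end-to-end acceptance tests.
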