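# warfinr

Individualized warfarin dosing from longitudinal anticoagulation data.

Warfarin therapy is steered by the international normalized ratio (INR):
patients return every few days to weeks, the INR is measured, and the daily
dose is adjusted to keep the INR in an indication-specific target range
(e.g. 1.8–2.3 after mechanical valve replacement, 2.0–3.0 for atrial
fibrillation). Dose requirements vary several-fold between patients,
largely through *CYP2C9* (clearance) and *VKORC1* (sensitivity)
polymorphisms, age, body size and co-medication. Cross-sectional
pharmacogenetic formulas ignore the visit history; `warfinr` models the
**next visit's INR** from both sources:

- a feedforward branch embeds the fixed covariates (age, height, weight,
  number of VKORC1 −1639 A alleles, number of CYP2C9 \*3 alleles,
  amiodarone use);
- an LSTM branch runs over the visit sequence, where visit *i* contributes
  the row (Dose<sub>i−1</sub>, INR<sub>i</sub>, Interval<sub>i+1</sub>,
  Dose<sub>i</sub>) and the supervised target INR<sub>i+1</sub>;
- the static embedding, the LSTM state and a skip connection from the
  current visit's row feed a linear head that emits one prediction per
  visit transition (masked many-to-many, minimizing mean squared error
  with Adam, early stopping on validation loss).

On top of the predictor the package provides:

- **dose recommendation** by inverting the model over the 16 quarter-tablet
  doses (0.625–6 mg): among candidates whose predicted INR lands in the
  target range, the one closest to the range midpoint is recommended
  (ties toward the lower dose);
- **evaluation**: banded prediction accuracy (fraction of predictions
  within 70–130% and 80–120% of the observed INR), MAE/MSE/RMSE, accuracy
  by follow-up window and by FDA genotype responder class, Pearson
  chi-square model comparisons, and Rosendaal time in therapeutic range;
- a **mechanistic cohort simulator** (drug accumulation → Hill inhibition →
  INR turnover, with genotype multipliers and closed-loop titration) that
  generates realistic longitudinal cohorts for end-to-end testing, since no
  public dataset with this structure exists.

See `vignette("warfinr-methods")` for the model, the simulator and every
numerical choice.

## Worked example

```r
library(warfinr)

params <- sim_params()                       # EC50 auto-calibrated
cohort <- generate_cohort(600, params, seed = 11)

model <- warfinr(cohort$statics, cohort$visits, warfinr_config(), seed = 5)
print(model)
#> Next-visit INR model (feedforward + LSTM hybrid)
#>   feature mode: full
#>   static features: age, height_cm, weight_kg, vkorc1_a, cyp2c9_star3, amiodarone
#>   parameters: 5301
#>   trained 42 epochs (best at 32), val MSE 0.3539 (standardized)
#>   held-out test: accuracy(70-130%) 95.1%, MAE 0.25 INR units on 390 predictions
```

The held-out accuracy is the fraction of next-visit predictions within
70–130% of the observed INR for test-set patients never seen in training;
MAE is in INR units. (Synthetic cohorts are cleaner than registry data, so
banded accuracies run higher than the ~70% typical of clinical records.)

Recommend the next dose for a test patient with a planned visit in 7 days:

```r
st  <- cohort$statics[cohort$statics$patient_id == model$split$test[1], ]
v   <- cohort$visits[cohort$visits$patient_id == st$patient_id, ]
rec <- recommend_dose(model, st,
                      data.frame(day = v$day, inr_observed = v$inr_observed,
                                 dose = v$dose_mg),
                      interval_next = 7)
rec$selected_dose   # 5.625  (mg/day; predicted INR 2.48, target 2.0-3.0)
```

`cross_validate()` reproduces the 10-fold protocol;
`closed_loop_evaluate()` replays the recommender against the heuristic
titration arm inside the simulator; `run_pipeline()` chains
simulate → train → evaluate → recommend into one seeded, logged run
(also available from a shell via `inst/cli/warfinr`).

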