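# ictsib

Stability-index (SI) estimation from center-of-pressure (CoP) sway
during the instrumented Clinical Test of Sensory Interaction with
Balance (i-CTSIB).

## What this is for

Clinical balance systems score standing balance as a dimensionless
stability index — zero means no sway, larger means more — across the
seven i-CTSIB conditions: eyes open/closed on a firm surface, one and
two foam pads, plus an eyes-open backwards-counting dual task. Those
systems are expensive; CoP can instead be measured with inexpensive
hardware (a pressure-sensing grid mat, or a four-load-cell board) and
the SI *estimated* from CoP sway features. `ictsib` is the complete
pipeline for that estimation, aimed at biomedical-signal and movement
scientists:

* CoP extraction: force-weighted centroid of a 68 × 48 pressure grid
  (23 Hz), or the four-corner lever formula
  `x = (L/2)·((tr+br) − (tl+bl))/total`,
  `y = (W/2)·((tl+tr) − (bl+br))/total`;
* preprocessing: per-axis linear detrend and a zero-phase 4th-order
  Butterworth bandpass, 0.1–4 Hz (−3 dB single-pass at both edges);
* ten sway features per 30-s trial: mean displacement, path, velocity,
  inter-sample distance, signed acceleration, the 95% confidence sway
  ellipse area `π · 5.991 · √(λ₁λ₂)` from the covariance eigenvalues,
  and four Welch spectral features (5%/50%/95% cumulative-power
  frequencies and the spectral centroid over the band);
* per-condition regression `SI ~ features` — ridge (the deployed
  family), SVM, GAM or regression tree — with hyperparameters chosen
  by Bayesian optimization (Gaussian-process surrogate,
  probability-of-improvement acquisition, 10-point Latin-hypercube
  initial design + 30 iterations) minimizing 5-fold CV RMSE, with
  subject-level 70/30 train/test splitting;
* deployment: raw-scale linear formulas exported as JSON, i-CTSIB
  session reports (overall SI = mean of per-condition SIs), and a
  Pearson device-agreement check;
* a calibrated synthetic sway generator (band-limited power-law
  Gaussian process, calibrated so the *pipeline's* expected mean
  velocity and ellipse area hit condition-typical targets) and a
  dual-device emulator, so everything is testable without clinical
  data.

The methods vignette (`vignettes/stability-index-methods.Rmd`)
documents every model, definition ambiguity, and calibration decision,
including why the velocity/area/median-frequency target triplet is
over-determined for any stationary sway process.

## Worked example

```r
library(ictsib)

# calibrate the generator and simulate a 40-subject cohort
cfg    <- suppressWarnings(calibrate_generator(generator_config()))
cohort <- generate_cohort(cfg, n_subjects = 40, seed = 7,
                          keep_trials = TRUE)

# subject-level split, one ridge model per condition
split  <- split_dataset(cohort$table, train_fraction = 0.7, seed = 7)
models <- train_si_models(split$train, "linear")

ev <- evaluate_model(models[["EO-firm"]],
                     split$test[split$test$condition == "EO-firm", ])
sprintf("EO-firm test r = %.3f, RMSE = %.3f (n = %d)", ev$r, ev$rmse, ev$n)
#> "EO-firm test r = 0.970, RMSE = 0.458 (n = 12)"

# score one subject's full session
trials <- lapply(ctsib_conditions(), function(cond)
  cohort$trials[[paste("S001", cond, sep = ":")]])
names(trials) <- ctsib_conditions()
run_ictsib_session(trials, models)
#> i-CTSIB session report for subject S001
#>   EO-firm    SI = 4.676
#>   EO-firm-DC SI = 7.257
#>   EO-foam1   SI = 6.550
#>   EO-foam2   SI = 9.015
#>   EC-firm    SI = 6.046
#>   EC-foam1   SI = 6.884
#>   EC-foam2   SI = 18.797
#>   overall SI (mean of 7 conditions) = 8.461
```

The per-condition SIs rise with task difficulty (eyes closed, foam
surfaces), and the overall SI is their mean — the quantity a clinician
would track over time. Test-set correlations near 0.97 reflect the
generator's ground-truth link (SI linear in the features at R² = 0.95)
being recovered by the ridge model on held-out subjects.

`export_linear_formula(models, "si_formula.json")` writes the fitted
per-condition coefficients (10 betas + bias each, raw feature scale);
`read_linear_formula()` reconstitutes models that predict identically,
which is how the formula ships to a measurement device.

A thin command-line front end with `simulate`, `extract-cop`,
`features`, `train`, `predict`, `session`, `agreement` and
`sample-size` subcommands is installed at `inst/cli/ictsib.R`
(`system.file("cli", "ictsib.R", package = "ictsib")`).

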