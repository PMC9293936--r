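# icpdyn

Dynamic 30-day mortality prediction for ICU-monitored traumatic brain
injury (TBI) patients, from minute-resolution intracranial pressure (ICP)
and mean arterial pressure (MAP) series.

Severe TBI patients are monitored invasively for days; sustained
intracranial hypertension is the main driver of death, and cerebral
perfusion pressure, CPP = MAP − ICP, is the pressure actually available to
perfuse the brain. `icpdyn` is for researchers who want a risk estimate
that is *re-computed as monitoring accrues* — every 8 h from 24 h to 120 h
after admission — rather than a single admission-time score, and who need
the whole pipeline (preprocessing, feature engineering, training,
time-dependent evaluation) reproducible and testable without access to
restricted ICU databases.

## The model

Each pressure signal s ∈ {ICP, MAP, CPP} is reduced, at prediction time
*t*, to per-window statistics (mean, signed consecutive-difference mean
`diff`, population variance `var`, `q90`/`q10` percentiles, and
threshold-fraction features `ht20`/`lt10` for ICP and `ht120` for MAP)
under three aggregations:

- **begin** — the statistic over the first 24 h window `[0, 24 h)`;
- **end** — over the trailing 8 h window `[t − 8 h, t)`;
- **coef** — the OLS slope of the statistic computed in rolling 4-h
  windows (1-h stride) from the start of monitoring up to *t*.

Together with age in decade bins (`agec`) this yields 54 + 1 candidate
features. A single logistic regression with **constant coefficients**
β is fit on rows pooled across prediction times,

  logit P(death within 30 days | x(t)) = β₀ + βᵀ z(x(t)),

with z-scored features, so the risk trajectory of a patient comes entirely
from the time-varying features. Features are chosen by recursive feature
elimination (drop the smallest |standardized coefficient|, score each
feature count by mean out-of-fold AUC) under stratified *patient-level*
cross-validation. Evaluation is time-dependent: AUC(t), AUPRC(t),
accuracy(t), and — calibrated to the clinical cost of a wrong death call —
the false-positive proportion fp/(fp + tp) (share of predicted deaths who
survived) and false-negative proportion fn/(fn + tn), at decision
thresholds 25/50/75%.

Because the underlying ICU cohorts are access-restricted, the package
includes a calibrated synthetic cohort generator (`generate_cohort()`)
producing minute-gridded mean-reverting ICP/MAP series whose latent
severity drives both outcome and a slow non-survivor ICP drift, plus block
missingness and out-of-range artifacts; presets mimic the published
demographics of the training, Stockholm and eICU cohorts.

## Worked example

```r
library(icpdyn)

sim    <- generate_cohort(generator_config("training", n_patients = 120, seed = 2024))
cohort <- prepare_cohort(sim$vitals, sim$metadata)
feats  <- featurize(cohort)
model  <- fit_dynamic_model(feats, training_config(seed = 1,
                                                   rfe_grid = c(2, 5, 10, 20, 40, 55)))
preds  <- predict_risk(model, feats)
curves <- metric_curves(preds, cohort$patients)
dplyr::filter(curves, threshold == 0.5, t_h %in% c(24, 72, 120))
```

which prints (abridged):

```
generate_cohort: 120 patients (preset 'training'), observed mortality 15.0%
exclude_extremes: removed 4718 of 617777 samples (icp=4559, map=159)
prepare_cohort: 120 of 120 patients eligible (age >= 16, ICP span >= 24 h)
featurize: 1059 (patient, time) rows, 55 candidate features
fit_dynamic_model: selected 20 of 55 candidate features (mean CV AUC 0.748)

    t_h n_evaluated   auc auprc accuracy fp_rate fn_rate
1    24         120 0.862 0.696    0.908   0.182  0.0826
2    72          84 0.943 0.834    0.940   0.111  0.0533
3   120          37 0.917 0.817    0.946   0.25   0.0303
```

Reading it: extreme pressures (ICP > 100 or < 0 mmHg, MAP > 150 or
< 20 mmHg — injected artifacts and sub-zero excursions) were removed
before CPP derivation; all 120 synthetic patients clear the age ≥ 16 /
ICP ≥ 24 h eligibility gate. The in-sample curves show risk estimates
sharpening as monitoring accrues (`auc`, `auprc`), the shrinking evaluated
population (`n_evaluated` — patients whose monitoring ended are excluded
from later time-points, never imputed), and at the 50% threshold the share
of predicted deaths who actually survived (`fp_rate`) alongside the share
of predicted survivors who died (`fn_rate`). Held-out performance comes
from `run_internal_cv()`, which repeats feature selection inside every
fold. `autoplot()` methods draw the metric curves and the signed feature
importances; the `icpdyn` script under `inst/cli/` exposes
`simulate / featurize / train / predict / evaluate / pipeline`
subcommands.

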