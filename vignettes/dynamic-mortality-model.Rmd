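---
title: "Dynamic mortality prediction from pressure monitoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic mortality prediction from pressure monitoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icpdyn)
```

## The problem and the model

Patients with severe traumatic brain injury are monitored invasively in
the ICU for days. Intracranial pressure (ICP) and mean arterial pressure
(MAP) arrive as 1–5-minute median values; cerebral perfusion pressure is
derived as CPP = MAP − ICP. The clinical question is dynamic: *given
everything monitored so far, what is this patient's risk of death within
30 days of admission?* — re-asked every 8 hours from 24 h to 120 h.

`icpdyn` answers it with a deliberately transparent model: one logistic
regression with coefficients that are **constant across prediction
times**, applied to features that summarise the monitoring history up to
the prediction time. All temporal dynamics live in the features; the
model itself never changes. This keeps the estimator auditable (a single
coefficient vector with signs a clinician can read) while letting the
risk track the physiology.

### The feature grammar

Each signal is reduced to per-window statistics:

| statistic | definition | unit |
|---|---|---|
| `avg` (rendered plain: `icp_end`) | arithmetic mean | mmHg |
| `diff` | mean of *signed* consecutive differences of in-window samples | mmHg/sample |
| `var` | population (1/n) variance | mmHg² |
| `q90`, `q10` | 90th / 10th percentile, linear interpolation | mmHg |
| `ht20`, `lt10` (ICP only) | fraction of samples strictly > 20 / < 10 mmHg | — |
| `ht120` (MAP only) | fraction strictly > 120 mmHg (severe hypertension) | — |

under three aggregations: **begin** (the statistic over the first 24-h
window), **end** (over the trailing 8-h window before the prediction
time) and **coef** (the OLS slope, in statistic units per hour, of the
statistic evaluated in rolling 4-h windows from monitoring start up to
the prediction time). With age in decade bins (`agec`, clipped to 1–9)
the default grammar enumerates 3 signals × 5 statistics × 3 aggregations
+ 3 threshold features × 3 aggregations + 1 = **55 candidates**.

Design points that were genuinely open, and how they were fixed:

- **Rolling-window stride.** "Rolling 4-h windows" does not pin a
  stride. We use a 1-hour stride with windows ending on whole hours
  (4 h, 5 h, …, t), giving the 24-h prediction a 21-point trend while
  bounding compute. The stride, window lengths and thresholds are all
  fields of `feature_grammar()`.
- **`begin`/`end` operate on raw in-window samples**, not on per-4-h
  summaries: they are defined as statistics of a single derived window.
- **`diff` is signed.** Its telescoping identity
  (mean diff = (last − first)/(n − 1)) makes it a cheap slope proxy; an
  absolute-difference variant sits behind `diff_absolute = TRUE` since
  the sign convention is a modelling choice.
- **`min`/`max` are implemented but excluded from the default grammar**
  (`include_minmax = TRUE` restores them, 73 candidates): the default
  grammar is the one that reproduces the 54-signal-feature count.
- Percentile type (linear interpolation between order statistics) and
  the 1/n variance are fixed for reproducibility; neither materially
  affects downstream selection.

### Preprocessing contract

Time is integer minutes from ICU admission; every window is half-open
`[a, b)`, so no sample is double-counted at a boundary. Raw timestamps
round half-up to the minute grid and same-minute duplicates collapse to
their median, mirroring how bedside databases store 1–5-min medians.
Extreme values are removed with *strict* inequalities — ICP > 100, ICP
< 0, MAP > 150, MAP < 20 mmHg — so boundary values survive; CPP is
derived afterwards on the minute-wise intersection and carries no filter
of its own. Missing minutes are never imputed: a feature whose window
holds no samples is missing, and a patient missing any selected feature
at a prediction time is excluded from that time-point's estimate.

Eligibility ("adult, at least 24 h of ICP data") is interpreted as
monitoring *span* — last ICP sample at or beyond minute 1440 — with a
cumulative-time alternative and an optional minimum-coverage fraction
available in `is_eligible()`. One boundary subtlety: with the half-open
120-h horizon a fully monitored patient's last sample sits just short of
minute 7200, so a scheduled prediction time counts as "monitored
through" when the last sample falls within 5 minutes (the coarsest
storage resolution) of it; otherwise the 120-h prediction would be
structurally unreachable.

### Training

Rows are pooled across prediction times — one row per (patient, time)
with the patient's 30-day outcome repeated — which is the simplest
scheme consistent with constant coefficients. Two consequences are
handled explicitly:

- **Leakage.** Cross-validation always splits by *patient* (stratified
  on outcome), never by row, so a patient's 32-h row cannot train the
  model that scores their 24-h row.
- **Weighting.** A patient monitored longer contributes more rows; this
  equals case-weighting by follow-up length and is tested against a
  weighted `glm()` oracle.

The fit itself is maximum-likelihood logistic regression on z-scored
features with a weak L2 ridge (default λ = 10⁻⁶ per observation) so that
separation or collinearity in small pooled cohorts still yields finite,
deterministic coefficients; at this strength the coefficients agree with
`glm()` to five decimals, and plain ML is recovered by `lambda = 0`.
Zero-variance features (e.g. `map_ht120_*` in small cohorts, where
MAP > 120 mmHg never occurs) are dropped with a warning.

Feature selection is recursive elimination: repeatedly refit and drop
the feature with the smallest absolute standardized coefficient; each
candidate count is scored by mean out-of-fold AUC under the stratified
patient-level folds, ties breaking toward fewer features. The criterion
(|standardized β|) and the score (AUC) are the package's choices; the
fold seed is recorded in the model artifact because the selected subset
legitimately varies with fold randomization.

### Evaluation

Metrics are computed per prediction time over the patients who *have* a
prediction there, and the evaluated n is always reported: attrition
(death, discharge, missing windows) changes the population composition
over time, and hiding that would flatter the late-time curves. AUC is
the pairwise concordance probability with half-credit ties (mid-rank
formula, tested against the O(n²) oracle); AUPRC uses a step-wise sweep
over unique thresholds — tied scores enter together — so a constant
scorer earns exactly the prevalence, and the optimistic linear PR
interpolation is avoided.

`fp_rate` and `fn_rate` follow the predictive-value reading: fp/(fp+tp),
the share of patients *flagged as dying* who survived (1 − precision),
and fn/(fn+tn), the share of predicted survivors who died. That is the
quantity a bedside user of a death prediction cares about. The
sensitivity/specificity complements fp/(fp+tn), fn/(fn+tp) are available
via `convention = "classic"` since prose definitions of "fp rate" are
ambiguous. Classification is strict: a risk *above* the threshold flags
death; a tie classifies as survival, deterministically.

## The synthetic cohort generator

No public minute-resolution TBI neuromonitoring cohort exists, so the
generator is a first-class, tested module, not a fixture. Per patient:

1. **Age** from a two-piece normal solved to hit the preset median and
   IQR exactly (training preset: 46 (28, 59) years), clipped to 16–95.
2. **Severity** ~ N(0, 1); **outcome** ~ Bernoulli(plogis(a + 1.5·s))
   with a solved numerically so the cohort mortality converges to the
   preset target (training: 17%).
3. **Monitoring duration**: a *censored* normal — a Normal(μ, σ) parent
   clipped to [24, 120] h with point masses at the bounds, (μ, σ) solved
   so the censored distribution's mean/SD equal the preset 90.7/31.4 h.
   A *truncated* normal cannot represent these moments (no distribution
   supported on a 96-h interval has SD 31.4 h around a mean of 90.7);
   censoring is also the clinically faithful mechanism: monitoring
   simply continues past the 120-h study horizon and is recorded at it.
4. **ICP**: an Ornstein–Uhlenbeck (mean-reverting) process, exactly
   discretised at the 2-min sampling grid, around a per-patient level
   (baseline 12 ± 3 mmHg between patients, + 2 mmHg per severity SD)
   plus, for non-survivors, a drift of 0.08 mmHg/h per severity SD.
   That drift is the generator's *sole* time-growing signal: it is what
   makes "discrimination improves with monitoring time" a designed-in,
   testable property rather than an accident of noise.
5. **MAP**: an independent OU process (85 ± 7 mmHg between patients,
   8 mmHg within); CPP therefore inherits ICP's signal. An optional
   `map_outcome_coupling` exists for sensitivity analyses.
6. **Corruption**: per-signal missing blocks (1 block/24 h of 60 min —
   conservative guesses, exposed in config, not data-derived) and
   artifact spikes (0.5/1000 samples) drawn strictly outside the
   plausibility limits, so the exclusion filters are always exercised.
7. **Death truncation**: non-survivors stop being monitored at a
   simulated death time (lognormal, median ≈ 140 h, floored at the 24-h
   eligibility bound), reproducing realistic attrition; it can be
   switched off to study its effect on late-time metrics.

What the generator does **not** emulate: plateau waves and other
mechanistic ICP dynamics, pressure autoregulation (no ICP–MAP coupling),
waveform-resolution structure, and the clinical covariates (GCS, CT
classes) that the model does not use. Passing tests therefore show that
the *pipeline* behaves correctly on data with the assumed statistical
structure — monotone severity effects, smooth mean-reverting noise,
benign missingness — not that the model attains any particular
performance on real neuromonitoring data, where artifacts are
structured, missingness is informative and severity is not univariate.

## Numerical and degenerate-input choices

- Windows with no samples give missing statistics; single-sample windows
  define level statistics but leave `diff`/`var` missing; trend slopes
  need at least two non-missing rolling windows and a non-degenerate
  time spread.
- The IRLS fit cold-starts at β = 0, clamps working weights at 10⁻¹⁰,
  and stops on a 10⁻¹⁰ relative deviance change — refits are bitwise
  identical.
- Single-class cohorts refuse to fit; folds refuse to build when a class
  has fewer patients than folds.
- All stochastic steps (cohort generation, fold shuffles, inner RFE
  shuffles) flow through explicit integer seeds stored in the artifacts;
  inner-CV seeds derive deterministically from the outer seed and fold
  index.

## Problem sizes used by the test suite

The suite exercises the full pipeline at the preset cohort size (686
patients) for the end-to-end discrimination-signature check, 2,000
pooled rows for feature-selection recovery (5 planted signals against 50
noise features), and 10,000 rows for coefficient recovery; unit tests
run on cohorts of 40–250 patients. These sizes are chosen so the whole
suite completes in a few minutes while keeping each statistical
assertion's sampling error far from its decision boundary.

## Known limitations

- The exact published 54-feature list lives in supplementary material we
  do not reproduce; the default grammar matches the printed count and
  every published selected-feature name, but a symbol-by-symbol audit is
  impossible, so the grammar is configurable rather than asserted.
- Constant-coefficient pooling is one consistent reading of the
  published training scheme; per-time fits with coefficient tying are a
  plausible alternative the package does not implement.
- fp/fn-rate denominators follow the predictive-value reading of the
  published prose; both conventions are computed because the formulas
  are not printed.
- The generator's missingness and artifact rates are plausibility
  defaults, not estimates from any cohort.
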