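---
title: "Forecasting post-bariatric hypoglycaemia from CGM: models, alarms and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting post-bariatric hypoglycaemia from CGM: models, alarms and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbhcast)
```

## The problem

Post-bariatric hypoglycaemia (PBH) is a late complication of gastric
bypass surgery: meals trigger rapid glucose rises followed, typically
90–150 minutes after intake, by sharp drops below the Level-2
hypoglycaemia threshold of 54 mg/dL. The clinical need is a short-term
warning — minutes, not hours — derived from continuous glucose
monitoring (CGM) alone, since any extra input (meal logging, wearables)
adds user burden. `pbhcast` implements that pipeline end to end:
preprocessing, forecasting, alarm generation, event-based scoring, and
hyperparameter tuning, plus a synthetic PBH-CGM generator so everything
can be exercised and tested without patient data.

Everything operates on a 5-minute sample grid, the native CGM rate. A
prediction horizon (PH) of `k` steps means `5k` minutes ahead, up to 30
minutes — beyond that the postprandial dynamics of PBH make pointwise
glucose prediction unreliable.

## Preprocessing: the causal asymmetry

Raw sensor exports are irregular: jittered timestamps, duplicates, gaps
from transmission failures. `align_cgm()` snaps samples to the grid
(nearest slot within ±150 s; halfway ties go to the earlier slot,
equidistant samples to the earlier sample). Two fills then apply, and the
asymmetry matters:

* **Training** data may be repaired offline, so interior gaps shorter
  than 30 minutes are linearly interpolated (`interpolate_gaps()`); the
  30-min boundary is strict — a gap of exactly 30 min stays missing.
* **Validation and test** data emulate deployment, where the future is
  unavailable: `causal_fill()` performs zero-order hold only, repeating
  the last seen value. Leading gaps stay missing. The fill is idempotent
  and provably causal (the test suite perturbs future samples with a
  sentinel and asserts nothing upstream changes).

`split_cgm()` cuts each subject chronologically at the floor of the
cumulative 70/15/15 fractions; `prepare_split()` applies the asymmetric
fills. Subjects with 10 days or less of observed data
(`cgm_eligible()`) are conventionally excluded from population fits.

## The recursive AR forecaster

The core model is deliberately minimal: first-order autoregression
`y(t) = a·y(t−1) + e(t)` whose single coefficient is re-estimated at
every sample by exponentially weighted recursive least squares. The
forgetting factor `mu` in (0, 1) discounts a sample `tau` steps old by
`mu^tau`; the effective memory is `tau = 1/(1 − mu)`. At the default
`mu = 0.675`, `tau ≈ 3.08`: roughly the three most recent samples drive
the estimate, so the coefficient swings quickly when a post-meal drop
begins — exactly the regime where warning time is won. The cost is noise
sensitivity: the same adaptivity that tracks real drops also chases
sensor noise, which is why the rAR's pointwise error (MAE) is the worst
of the model family while its event-level performance is the best. The
alarm threshold, tuned below, absorbs that bias.

Numerically the update is carried in information form (tracking
`R = 1/P`): it is algebraically identical to the textbook covariance
gain form, but `P` grows like `mu^{−t}` and the covariance recursion
accumulates floating-point error over long runs, while the information
form matches the exact batch weighted-least-squares solution to machine
precision at every step (a property the test suite asserts at 1e-8
against a direct-summation oracle). The state is initialised at
`a = 1` (persistence — the safe cold start: before evidence arrives, the
forecast is flat) with weak prior `P = 1e3`, and no forecast is issued
until 3 updates have been absorbed. The state is kept per subject and
reset after a missing run of 30 minutes or more; held (zero-order-hold)
values do update the state otherwise, since that is what a deployed
estimator would see. Multi-step forecasts iterate the one-step
prediction: `yhat(t + k | t) = a^k y(t)`.

`fit_rar()` selects `mu` population-wise by grid search (default grid
0.1–0.9 in steps of 0.025) on the summed one-step squared prediction
error of the training pass — the prediction-error method. Only `mu` is
population-wise; `a(t)` always adapts per subject.

## The comparison families

* **ARIMA(3,1,1)** (`fit_arima_pem()`): one population coefficient set,
  fitted by minimising the conditional sum of squared one-step errors.
  Each contiguous non-missing segment is an independent realisation — no
  error term spans a gap or a subject boundary (fitting one gapped
  subject and two subjects holding the same segments gives identical
  coefficients; a suite test asserts this). With `d = 0` a level term is
  included, estimated as the pooled segment mean. Causality and
  invertibility are checked on the fitted polynomials. Multi-step
  forecasts iterate the one-step predictor with future innovations at
  zero and integrate back to the glucose scale.
* **Windowed regressors** (`fit_windowed()`): sequence-to-sequence maps
  from the last 12 samples (60 min; twice the output span, the common
  choice in CGM forecasting) to the next 6. Supervised pairs are emitted
  only where all 18 samples are contiguous and non-missing
  (`make_supervised()`). Families: random forest (100 trees, depth ≤ 15,
  ≥ 10 samples per split), leaf-wise gradient-boosted trees (200 rounds,
  31 leaves, learning rate 0.02), and a feed-forward network (hidden
  layers 32 with ELU and 16 linear, 6 linear outputs, mean-squared-error
  loss, RMSprop at 1e-5, batches of 32, at most 300 epochs with
  early stopping after 30 stalled epochs on validation loss). The tree
  families fit one independent model per output step — deterministic
  under a seed. Inputs are standardised by the training-set global
  mean/SD stored with the model. Recurrent families (LSTM, CNN-LSTM) are
  reserved names in the contract; this package does not train them, and
  their `fit_windowed()` errors immediately. Glucose enters the linear
  models in raw mg/dL — no detrending or standardisation.

All families sit behind `forecast_stream()`, which simulates real-time
acquisition: one forecast per origin where the model's history
requirement is met, computed strictly from samples at or before the
origin. Strict causality of every family is part of the test suite.

## From forecasts to alarms

`generate_alarms()` raises an alarm at origin `t` iff

1. the forecast at exactly PH is below the **AlarmLevel**
   (`yhat(t+PH|t) < AlarmLevel`, strict);
2. no alarm was raised in the preceding PH minutes (shut-off; repeated
   alerts for one impending event are burden, not information);
3. the current value is at or above 54 mg/dL — once the subject is
   already hypoglycaemic a *predictive* alarm is moot; suppression lifts
   the moment glucose recovers.

The alarm test uses the single forecast at PH rather than "any step up
to PH": PH is the operative, tuned horizon, and collapsing over steps
would blur what is being tuned. An "any-step" variant can be emulated by
lowering PH. Condition 3 applies even at an onset's first sample — the
strict reading; the alternative (allowing an alarm concurrent with the
first sub-54 sample) would label as "predictive" an alarm with zero
warning time. Origins whose current sample is held (ZOH) may alarm — a
real-time system must act on held values — and are flagged `from_held`
so their share can be reported.

AlarmLevel is a genuinely free hyperparameter, distinct from the 54
mg/dL clinical threshold. Adaptive linear models overshoot falling
glucose (favouring AlarmLevels below 54); smoothing regressors
overestimate lows (favouring AlarmLevels above it).

## Event-based scoring

`detect_episodes()` defines a Level-2 episode as a maximal run of
samples strictly below 54 mg/dL, with runs separated by less than 15 min
merged, and merged runs shorter than 15 min (3 samples) discarded — the
international CGM consensus event definition; both constants are
arguments. Missing samples never count as below threshold.

`match_alarms()` scores alarms and episodes asymmetrically, which
mirrors how the quantities are used clinically:

* an **alarm** at `s` is a true positive iff an episode **onset** falls
  in `(s, s + 45]` minutes, else a false positive — precision counts
  alarms;
* an **episode** is detected iff some alarm falls in
  `[onset − 45, onset)`, else a false negative — recall counts events;
* the **time gain** of a detected episode is `onset` minus the earliest
  alarm in its window, hence in (0, 45].

F1 is the harmonic mean of precision and recall; zero-denominator cases
return 0 with an explicit flag rather than NaN. False alarms per day
divide by the calendar span of the evaluated segment, missingness
ignored. Time-gain summaries use nearest-rank (type-1) quartiles, which
are robust for the small per-split event counts. `mae()` is the mean of
absolute errors `|y(t+PH) − yhat(t+PH|t)|` over origins whose target
sample exists (the absolute value sits inside the mean; a published
variant typesets it outside the sum, which would instead measure net
bias). By default held targets count — that is what a deployed system is
scored against — and `target_status` can restrict scoring to measured
samples only.

`glucometrics()` reports the standard cohort summaries (mean, SD,
time-in-range bands, episode counts/durations) over observed samples
only, plus MAGE: turning points from a sign-change scan, sub-SD
oscillations pruned smallest-first, and the mean taken over remaining
peak-to-nadir amplitudes exceeding one SD of the trace.

## Tuning PH and AlarmLevel

`tune_alarms()` is an exhaustive grid search — PH over {15, 20, 25, 30}
min and AlarmLevel over 35–80 mg/dL in 1 mg/dL steps by default —
regenerating alarms and recomputing all metrics per cell on the
validation split, and maximising F1. Ties are broken by lower FP/day,
then larger PH (more warning), then lower AlarmLevel: alarm burden
first. The search is deterministic and invariant to grid order; the
suite cross-checks every cell against an independent nested-loop
recomputation. `pr_curve()`/`autoplot()` expose the precision–recall
trajectories per PH. Raising AlarmLevel generally moves a model from
high-precision/low-recall to the opposite corner; recall is weakly
increasing in AlarmLevel on fixtures here, though the shut-off can in
principle suppress a better-placed later alarm, so monotonicity is
checked empirically rather than assumed.

## The synthetic PBH generator

Because clinical PBH datasets are not publicly deposited, the package
ships a generator (`simulate_cohort()`) whose defaults emulate the
published cohort statistics this pipeline targets: mean glucose near 107
mg/dL, ~90% of time in 70–180 mg/dL, about 4 Level-2 episodes per 10
days with median duration 25 min, and ~1% of time below 54 mg/dL.

Construction per subject: a mean-reverting basal process around 100
mg/dL (SD 5 mg/dL, reversion half-life 2 h — stable overnight CGM
behaviour); four meals per day drawn in evenly spaced daytime windows;
per meal a smooth cosine rise of 60–140 mg/dL peaking at 30–60 min and
decaying symmetrically; with probability 0.10 per meal a hypoglycaemic
dip 90–150 min post-meal, holding 5–15 mg/dL below 54 for 15–35 min with
half-step shoulders at or above 54 (so time-below-54 equals the drawn
duration exactly); AR(1) sensor noise (marginal SD 3 mg/dL, coefficient
0.7, a Dexcom-like error structure); clipping to the 40–400 mg/dL sensor
range; and Poisson-seeded data gaps (0.3/day, 10–120 min). Ground truth
records the below-54 runs of the deterministic (pre-noise, pre-gap)
curve, so with noise and gaps disabled `detect_episodes()` recovers the
intended episodes exactly — the generator–detector round trip is a suite
invariant, as is bit-reproducibility from `(seed, subject index)`.

The waveform itself is invented; calibration is to the cohort
*statistics*, not to any real trace shape. Two honest gaps: simulated
MAGE runs high (~115 mg/dL vs ~55 published) because every meal
excursion is large and clean, and the dip entry is sharper than real
postprandial trajectories. Consequently event-level results on synthetic
cohorts (F1 well above 90% for tuned rAR) overstate what the same code
achieves on clinical data, where published F1 for the best model is
~73%. Passing tests here demonstrates correctness of the machinery and
calibration of first-order glucometrics — not clinical performance.

The `clairvoyant_model()` oracle ("forecasts" equal to true future
values) closes the loop: on noiseless cohorts it must achieve recall
100%, precision 100%, FP/day 0 and MAE 0 through the full
alarm-and-matching pipeline, and the suite asserts exactly that.

## Numerical and design notes

* Grid tolerance ±150 s with earlier-slot/earlier-sample tie-breaks;
  duplicate raw timestamps are averaged; glucose outside 20–500 mg/dL is
  rejected at read time.
* Problem sizes in the tests are chosen for tight, deterministic checks:
  oracle equivalences run on hundreds of short random sequences;
  parameter recovery uses n = 1000 (AR(1), 20 replicates) and n = 5000
  (ARIMA); the calibration check simulates the full 47-subject default
  cohort once.
* The ARIMA CSS objective is optimised by BFGS from Hannan–Rissanen-style
  starts plus small MA restarts; non-convergence is an error carrying the
  optimiser code, never a silent fallback.
* The feed-forward trainer is plain matrix algebra with He
  initialisation, so network fits are bit-reproducible under a seed with
  no external runtime.
* rAR/ARIMA models persist as human-readable JSON (`write_model()` /
  `read_model()`).

## Limitations

CGM-only input is a design choice, not an oversight: meal times, heart
rate or activity could help but cost user burden and synchronisation
complexity. The package does not model insulin–glucose physiology, does
not implement recurrent deep families, does not provide dosing advice,
and its synthetic cohorts — however calibrated — are not a substitute
for clinical validation.
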