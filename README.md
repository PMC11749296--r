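# pbhcast

Short-term forecasting of **post-bariatric hypoglycaemia (PBH)** from
continuous glucose monitoring (CGM) data alone.

After Roux-en-Y gastric bypass, a subset of patients develops PBH: rapid
meal-induced glucose rises followed by sharp drops below 54 mg/dL,
typically 90–150 minutes after eating. Because the drops are fast, a
decision-support system has only minutes to warn the patient. `pbhcast`
implements the complete CGM-only prediction pipeline for this problem —
for researchers developing hypoglycaemia forecasting algorithms and for
anyone who needs an event-based evaluation harness for predictive alarms.

## What is in the package

**Causal preprocessing** (`read_cgm()`, `align_cgm()`,
`interpolate_gaps()`, `causal_fill()`, `split_cgm()`): raw sensor exports
are aligned to a 5-min grid; training data get short (< 30 min) gaps
linearly interpolated, while validation/test data are filled by causal
zero-order hold only — a deployed system cannot look ahead.

**Forecasters** (`forecast_stream()` over a uniform contract): the
centrepiece is the run-to-run **recursive AR(1)** model (`rar_model()`),
whose coefficient is re-estimated at every new sample by exponentially
weighted recursive least squares. With forgetting factor μ, a sample τ
steps old carries weight μ^τ, so the effective memory is τ = 1/(1 − μ);
at the default μ = 0.675 roughly the 3 most recent samples drive the fit,
which is what lets the model track fast post-prandial drops. Forecasts
iterate the one-step prediction: ŷ(t + k·5 min | t) = a^k · y(t).
Alongside it: a population **ARIMA(3,1,1)** fitted by minimising the
one-step prediction error over contiguous segments (`fit_arima_pem()`),
and windowed multi-step regressors (`windowed_spec()`, `fit_windowed()`):
random forest, leaf-wise gradient-boosted trees, and a feed-forward
network (32/16 hidden units, ELU + linear, RMSprop), each mapping the
last 60 min of CGM to the next 6 samples (30-min horizon).

**Alarms** (`generate_alarms()`): an alarm fires when the forecast at the
prediction horizon PH falls below a tunable **AlarmLevel**, with a
shut-off that ignores re-triggers within PH minutes of a previous alarm
or while the current value is already below the 54 mg/dL hypoglycaemia
threshold.

**Event-based evaluation** (`detect_episodes()`, `match_alarms()`,
`precision_recall_f1()`, `fp_per_day()`, `time_gain_summary()`, `mae()`,
`glucometrics()`): an alarm is a true positive if an episode starts
within the following 45 minutes; an episode is detected if an alarm
preceded its onset by at most 45 minutes; the time gain is the distance
from the earliest such alarm to onset.

**Tuning** (`tune_alarms()`): grid search over PH ∈ {15, 20, 25, 30} min
and AlarmLevel ∈ [35, 80] mg/dL, maximising F1 on the validation split.

**Synthetic PBH cohorts** (`sim_config()`, `simulate_cohort()`,
`clairvoyant_model()`): a generator calibrated to published PBH cohort
glucometrics (mean glucose ≈ 107 mg/dL, ≈ 4 Level-2 episodes per 10 days
of median duration 25 min) with ground-truth event logs, so the whole
pipeline is testable without patient data.

## Worked example

```r
library(pbhcast)

cohort <- simulate_cohort(sim_config(n_subjects = 6, days_per_subject = 39, seed = 7))
trace  <- cohort_trace(cohort)
splits <- prepare_split(split_cgm(trace))      # 70 / 15 / 15, asymmetric fills

model  <- rar_model(mu = 0.675)
val_fc <- forecast_stream(model, splits$validation)
tuning <- tune_alarms(val_fc, splits$validation)
best_cell(tuning)
#>   ph_min alarm_level precision recall    f1 fp_per_day tg_median_min n_alarms
#> 1     15          62       100   87.5  93.3          0             5        7

test_fc <- forecast_stream(model, splits$test)
cfg     <- alarm_config(ph_min = 15, alarm_level = 62)
alarms  <- generate_alarms(test_fc, splits$test, cfg)
events  <- detect_episodes(splits$test)
m       <- match_alarms(alarms, events, monitored_days = monitored_days(splits$test))
glance(m)
#>   precision recall    f1 fp_per_day tg_median_min tg_q25_min tg_q75_min n_alarms n_events
#> 1      90.9    100  95.2     0.0570             5          5          5       22       19

mae(splits$test, test_fc, 15)
#> [1] 12.36
```

Reading the numbers: on this synthetic test split the tuned rAR alarms
caught all 19 Level-2 episodes (recall 100%), 90.9% of its 22 alarms were
followed by a real event within 45 min, false alarms came at 0.057/day
(about one per 18 days), and the median warning arrived 5 min before
onset. The 15-min-ahead forecasts were off by 12.4 mg/dL on average —
close to what the recursive AR achieves on real PBH data at this horizon.
Synthetic traces are cleaner than real life, so event metrics here run
higher than on clinical data; see the methods vignette
(`vignettes/pbh-forecasting.Rmd`) for what the simulator does and does
not emulate.

A thin command-line front end over the same functions lives at
`inst/cli/pbhcast.R` (`simulate`, `forecast`, `alarms`, `evaluate`,
`tune` subcommands).

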