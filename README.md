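# tachynet

Early prediction of tachycardia onset from continuously monitored vital
signs.

`tachynet` is for researchers and clinical-informatics engineers who have
per-minute heart-rate (HR), respiratory-rate (RR) and SpO2 streams — from
ICU bedside monitors or ward-grade wearables — and want a tested,
end-to-end pipeline that labels tachycardia onset, learns to predict it
hours ahead, streams real-time risk scores with alarms, and transfers a
model trained in one care setting to another.

## The method

**Onset labeling.** Tachycardia onset is the first minute of any heart-rate
run satisfying a sustained-exceedance rule: HR > 100 bpm for ≥ 30 min,
HR > 130 for ≥ 20, or HR > 150 for ≥ 5.

**Features.** A trailing 2-hour observing window is sliced into 20-minute
sub-windows sliding by 5 minutes (21 steps). Each step is summarized by 21
statistics across the three channels — means, SDs, sums, least-squares
slopes, quantiles (0.1/0.3/0.7), the absolute energy

$$f_1 = \sum_i X_i^2,$$

the lag-$l$ autocorrelation

$$R(l) = \frac{1}{(n-l)\,\sigma^2}\sum_{i=1}^{n-l}(X_i-\mu)(X_{i+l}-\mu),$$

(averaged across channels at $l = 40$ over the full window), and the
third-order nonlinearity statistic

$$c_3(lag) = \frac{1}{n-2\,lag}\sum_i X_{i+2\,lag}\,X_{i+lag}\,X_i.$$

**Classifier.** The encoded static profile (age, gender, admission type,
first care unit, cardiovascular history — 11 values) is appended to every
time step, and a bidirectional LSTM (hidden size 32 per direction, dense
logistic head) maps the fused sequence to a risk score in [0, 1]. Training
is binary cross-entropy with minibatch Adam; the BiLSTM, backpropagation
through time and Adam are implemented in base R and gradient-checked
against finite differences. Positive training windows end one *forecast
range* (0–6 h) before onset and are replicated in 5-minute shifts;
negatives stride hourly across event-free records; classes are balanced
and split 80/20 by patient.

**Monitoring.** `stream_scores()` re-scores the trailing window every 5
minutes; `raise_alarm()` fires after a run of consecutive scores above a
threshold (default 0.40); `lead_time()` reports minutes of warning before
the detected onset.

A synthetic-cohort generator (AR(1) vitals, configurable pre-onset
prodrome, static profiles drawn from published cohort compositions) makes
the whole pipeline testable without access to protected clinical data.

## Worked example

```r
library(tachynet)

co  <- generate_cohort(cohort_params(n_patients = 100, prevalence = 0.3,
                                     seed = 42))
run <- run_pretrain(co$records, sampling = sampling_config(forecast_range = 2),
                    bootstrap_B = 200, seed = 42)
print(run)
#> <pretrain_run> train 228 / test 72 samples (hash 3c49ae6c)
#>        metric value ci_lower ci_upper
#> 1       auroc 0.991    0.969    1.000
#> 2 sensitivity 0.925    0.825    1.000
#> 3 specificity 0.969    0.906    1.000
#> 4    accuracy 0.944    0.875    1.000
#> 5   precision 0.974    0.925    1.000
#> 6          f1 0.949    0.897    0.988
```

A cohort of 100 synthetic patients (30 with a tachycardia event preceded by
a 6-hour vital-sign prodrome) is labeled, sampled at a 2-hour forecast
range, balanced and split by patient; the held-out AUROC of 0.991 says the
classifier almost perfectly separates pre-onset windows from event-free
ones two hours ahead on this synthetic signal.

Stream one event patient in real time:

```r
rec <- co$records[["P0010"]]                    # onset at minute 513
sc  <- stream_scores(rec, run$model)
al  <- raise_alarm(sc, monitor_config(threshold = 0.40, persistence = 2))
al$alarm_minute
#> [1] 245
lead_time(al$alarm_minute, 513)$minutes
#> [1] 268
```

The risk score crosses 0.40 during the prodrome and stays there: the alarm
fires at minute 245, 268 minutes before the onset at minute 513.
`plot_monitoring(rec, sc, al, onset = 513)` draws the heart-rate trace and
the score stream together.

## Package tour

| Stage | Functions |
|---|---|
| preprocessing | `downsample_to_minute`, `fill_missing`, `read_vitals_csv`, `as_patient_records` |
| onset labeling | `tachy_criteria`, `detect_onset`, `label_onsets` |
| features | `feature_registry`, `extract_sequence`, `abs_energy`, `autocorrelation`, `c3`, `ts_slope` |
| sampling | `sampling_config`, `build_samples`, `extract_positives`, `extract_negatives`, `balance_and_split`, `encode_static` |
| model | `tachynet`, `predict`, `finetune`, `random_search_cv`, `save_tachynet`, `load_tachynet` |
| monitoring | `monitor_config`, `stream_scores`, `raise_alarm`, `lead_time`, `plot_monitoring` |
| evaluation | `auroc`, `threshold_metrics`, `bootstrap_ci`, `metric_table`, `grouped_cv` |
| simulation | `cohort_params`, `prodrome_spec`, `generate_patient`, `generate_cohort`, `write_cohort_csv` |
| workflows | `run_pretrain`, `run_transfer`, `inst/cli/tachynet` |

The methods vignette (`vignettes/tachycardia-early-warning.Rmd`) documents
the model, its conventions and defaults, what the synthetic generator does
and does not emulate, and known limitations.
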