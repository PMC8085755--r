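---
title: "Early warning of tachycardia onset from continuous vital signs: methods"
author: "tachynet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Early warning of tachycardia onset from continuous vital signs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Tachycardia — a resting adult heart rate above 100 bpm — precedes and
accompanies serious deterioration in monitored patients, and continuous
monitoring (bedside monitors in critical care, wearable multi-sensor systems
on general wards) makes it possible to predict its onset rather than merely
alarm on it. `tachynet` implements a complete early-warning pipeline on
per-minute heart rate (HR), respiratory rate (RR) and oxygen saturation
(SpO2) streams plus a handful of static attributes from the patient record:
age, gender, admission type, first critical-care unit and cardiovascular
history.

The pipeline has five stages, each exposed as ordinary functions:

1. **Preprocessing** (`downsample_to_minute`, `fill_missing`,
   `as_patient_records`): per-second monitor samples are averaged per
   minute, minutes with more than 30 % null/zero samples are treated as
   missing, and missing minutes are filled causally by carrying the last
   observation forward.
2. **Onset labeling** (`detect_onset`): tachycardia onset is the first
   minute of any run of heart-rate values strictly above 100 bpm sustained
   for at least 30 minutes, above 130 for 20, or above 150 for 5.
3. **Feature extraction** (`extract_sequence`): a 2-hour observing window is
   sliced into 20-minute sub-windows sliding by 5 minutes (21 steps), each
   summarized by 21 statistical features.
4. **Classification** (`tachynet()`): a bidirectional LSTM over the
   21-step sequence, with the encoded static profile appended to every
   step, produces a risk score in [0, 1].
5. **Monitoring and evaluation** (`stream_scores`, `raise_alarm`,
   `metric_table`, `grouped_cv`): scores are streamed every 5 minutes,
   alarms fire on persistent threshold exceedance, and performance is
   reported with six metrics and bootstrap intervals.

## Onset labeling

"Above" is strict (`>`), and "sustained over D minutes" is read as run
length ≥ D: a 51-minute run at 110 bpm starting at minute 675 is labeled at
675 under the 100-bpm/30-minute rule, while a 29-minute run at 110 is not an
event. When several rules qualify, the earliest qualifying run start wins;
at an identical start the higher threshold is reported. Only the first
onset labels a record — the model predicts onset, not recurrence — though
`detect_onset(all_events = TRUE)` exposes later runs for bookkeeping.

## The feature set

Each 20-minute sub-window of each channel is summarized by members of eight
statistic families. Three deserve their formulas; for a window
$X_1,\dots,X_n$:

* absolute energy $f_1 = \sum_{i=1}^{n} X_i^2$;
* lagged autocorrelation
  $f_2:\; R(l) = \frac{1}{(n-l)\sigma^2}\sum_{i=1}^{n-l}(X_i-\mu)(X_{i+l}-\mu)$,
  with $\mu$ the window mean and $\sigma^2$ the *population* variance (the
  conventional normalization for $R$); a zero-variance window returns 0;
* third-order nonlinearity
  $f_3:\; c_3(lag) = \frac{1}{n-2\,lag}\sum_{i=1}^{n-2\,lag}
  X_{i+2\,lag}\,X_{i+lag}\,X_i$.

The default registry (`feature_registry()`) has 21 entries in fixed order:
ten for heart rate (mean, SD, sum, slope, $f_1$, $c_3$ at lags 2 and 3 —
the lag-2 entry carries the historical name `hr_c2` — and quantiles at
levels 0.1/0.3/0.7), five each for respiratory rate and SpO2, and one joint
feature, `all_autocorrelation`. Conventions the definitions leave open were
fixed once and oracle-tested: the "SD" features use the *sample* standard
deviation; quantiles interpolate linearly between order statistics; the
slope is the ordinary least-squares line against the minute index.

The joint autocorrelation uses lag 40, which no 20-sample sub-window can
support. It is therefore computed once per observing window — $R(40)$ over
the full 120 minutes, averaged across the three channels — and replicated at
every time step. This is the only geometry under which a lag of 40 is
feasible, and replication keeps every time step's vector the same length.
Ablation subsets (HR only: 10 features; HR plus one other channel: 15) are
available through the registry's `channels` argument; the joint feature
requires all three channels.

Minute indexing is 0-based from record start and windows are half-open,
`[end − 120, end)`: one convention had to be fixed, and this one makes a
window ending *at* the onset minute contain only pre-onset data.

## Building labeled samples

Negative samples come only from records with no detected onset: observing
windows ending at minute 120, 180, 240, … (a 1-hour stride). Positive
samples come from event records: the base window ends one *forecast range*
(0–6 h) before onset, and replication adds up to `replication_count` more
windows, each 5 minutes earlier than the last ("target replication"). The
replication default of 4 bounds the augmentation near the roughly 1.3:1
negative:positive ratio of realistic cohorts; shifting *earlier* rather
than later keeps every replicated window on the correct side of the
forecast boundary. Records shorter than the minimum monitoring duration
(14 h for the critical-care preset, 4 h for the ward preset) or from
patients aged 18 or under are excluded at assembly. Negatives are then
subsampled (seeded, without replacement) to the positive count, and the
set is split 80/20 *by patient*, so no patient's windows straddle the
split.

## The classifier

The static profile is encoded as 11 numbers: age, a male indicator, three
admission-type indicators, five care-unit indicators (all zero for ward
patients, who have no ICU stay) and a cardiovascular-history indicator.
This vector is appended to every time step's feature vector — the static
information is merged with the statistical features before the sequence
enters the network, rather than being injected only at one end — giving
32 inputs per step with the default registry.

The network is a bidirectional LSTM with 32 hidden units *per direction*
(the stated hidden size is taken as per-direction width). The final hidden
states of the two directions are concatenated and mapped by a dense
logistic layer to the risk score: the simplest standard head for sequence
classification. Training minimizes binary cross-entropy with minibatch
Adam (the field-default optimizer for this architecture), default learning
rate 2e-4, 20 epochs, batch 64. There is no deep-learning framework behind
this: the forward pass, backpropagation through time and Adam are written
in base R matrix code, and the analytical gradients are verified against
central finite differences in the test suite.

Normalization statistics (per-feature mean and SD of the sequence features,
plus the age column of the static vector; indicator columns and
zero-variance features pass through unscaled) are computed on the training
samples only and stored in the fitted object — scoring never touches the
statistics of new data. A fixed seed fixes initialization and batch order,
so fits are exactly reproducible.

Hyperparameter search (`random_search_cv`) draws uniformly from the grids
learning rate 1e-4…1e-2 in steps of 1e-4 and epochs 5…95 in steps of 10
("5 to 100 with an interval of 10" admits only the lattice points up to
95), scoring each draw by mean validation cross-entropy over patient-grouped
5-fold cross-validation.

## Transfer between care settings

`finetune()` continues optimization from pretrained weights with the
transfer defaults (learning rate 2e-4, 18 epochs, batch 32), recomputing
normalization statistics on the new cohort, whose feature scales differ.
A registry hash guards against finetuning across incompatible
featurizations. `run_transfer()` assesses the transferred model with
patient-grouped 5-fold cross-validation — each fold finetunes from the same
pretrained weights — and reports mean (SD) per metric, the appropriate
summary when the target cohort is too small for a held-out test set.

## Real-time monitoring

`stream_scores()` evaluates the model on the trailing 2-hour window every
5 minutes, beginning at minute 120; scoring is strictly causal, so
truncating the future never changes past scores. `raise_alarm()` fires at
the evaluation where a run of consecutive scores strictly above the
threshold (default 0.40) first reaches the persistence count (default 1 —
the period of persistence is a clinical choice the default leaves neutral).
Lead time is onset minus alarm minute; late alarms are reported as lead 0
with a `late` flag and missed events as `missed`, so monitoring summaries
can count them rather than drop them.

## Evaluation

AUROC uses the rank (Mann-Whitney) estimator with ties counted one half;
the five threshold metrics use the rule `score > threshold` with default
threshold 0.5 (configurable; nothing in the method fixes it). When no
sample is predicted positive, precision is reported as 0 with an explicit
flag rather than NaN. Confidence intervals use a class-stratified
percentile bootstrap (B = 1000) uniformly for all six metrics: stratified
resampling keeps both classes in every replicate, and the percentile method
is metric-agnostic and exactly reproducible under a seed.

## The synthetic cohort generator

No protected clinical data ships with the package, so every stage is
exercised on synthetic cohorts (`generate_cohort`). Each channel is a
stationary AR(1) process around clinical baselines — HR 75 (SD 8) bpm, RR
16 (SD 3), SpO2 97 (SD 1.5), AR coefficient 0.9 per channel, innovation
variance scaled so the marginal SD matches — reflecting the strong
minute-scale autocorrelation of real vitals. Static profiles follow the
published composition of the two study settings (critical care: 57.2 %
female, 79.8 % emergency admissions, 86.6 % cardiovascular history, five
care units; ward: 40.5 % female, 87.6 % elective, no care unit), and ages
are truncated normal draws around each setting's median.

Event patients receive a *prodrome*: linear ramps over the `lead` minutes
before onset (HR +15 bpm, RR +4, SpO2 −3 by default, HR noise inflated
1.5-fold) followed by a heart-rate plateau (115 bpm, 45 minutes) from
onset. The default lead of 360 minutes reflects the common clinical
observation that vital-sign deterioration begins 6–12 hours before serious
adverse events. Two constructions make the ground truth exact rather than
approximate: ramp values are capped at 100 bpm, so no qualifying run can
begin before the injected onset, and plateau values are floored just above
the threshold, so the injected run always qualifies. Real prodromes are of
course neither linear nor guaranteed — passing the recovery tests shows
the pipeline extracts a recoverable signal with the stated geometry, not
that real tachycardia is this predictable. The generator also makes no
attempt at mechanistic cardiorespiratory coupling, arrhythmia morphology,
artifact structure, or informative missingness.

All randomness flows from one cohort seed through derived per-patient
seeds, so a cohort is byte-reproducible and any single patient can be
regenerated from the truth table alone.

## Validation scale and numerical choices

The test suite validates the primitives against independent naive-loop
oracles (features: 1000 random windows at tolerance 1e-9; onset detection:
brute-force scan of every window on series up to 2000 minutes; AUROC:
brute-force pair counting up to 200 samples) and the whole pipeline
end-to-end on cohorts of 200 patients at 30 % prevalence: with the default
prodrome the held-out AUROC reaches at least 0.90 at a 2-hour forecast
range, and with all drifts zeroed it stays within [0.45, 0.55] (median of
three seeds) — the model finds the injected signal and nothing else.
Smaller cohorts (24–60 patients) back the faster workflow tests; these
sizes give stable behavior while keeping the default suite quick on a
single CPU.

Remaining numerical conventions: the logistic loss clamps probabilities at
1e-12 for finiteness; LSTM weights initialize uniformly in ±1/√H with the
forget-gate bias raised to 1; model bundles serialize weights as full-
precision JSON, so a round trip preserves predictions to ~1e-8.

## Limitations

The published headline numbers for this class of model (ICU AUROC ≈ 0.80
at a 6-hour forecast range; ward AUROC ≈ 0.96 after transfer) were obtained
on credentialed critical-care and hospital datasets that cannot be bundled;
this package reproduces the *method* and validates it on synthetic cohorts,
not those results. Forecast performance on the synthetic default decays to
chance once the forecast range pushes the observing window past the
prodrome start — qualitatively matching the published decay with forecast
range but by construction, not by physiology.
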