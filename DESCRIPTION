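Package: tachynet
Title: Early Prediction of Tachycardia Onset from Continuous Vital-Sign Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for early warning of tachycardia onset from continuously
    monitored vital signs (heart rate, respiratory rate, SpO2). Implements
    rule-based onset labeling (sustained heart-rate exceedance), sliding-window
    statistical feature extraction (mean, dispersion, slope, quantiles,
    absolute energy, lagged autocorrelation, third-order nonlinearity), fusion
    of static patient attributes with the windowed features, a bidirectional
    long short-term memory (BiLSTM) sequence classifier trained by
    backpropagation through time with the Adam optimizer, real-time risk-score
    streaming with persistence-gated alarms and lead-time reporting, grouped
    cross-validation and bootstrap-interval evaluation, transfer finetuning
    between care settings, and a synthetic-cohort generator with controllable
    pre-onset prodromes for end-to-end validation without access to protected
    clinical data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite, yaml
Suggests: testthat (>= 3.0.0), pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
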