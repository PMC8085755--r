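# Synthetic vital-sign cohorts with controllable tachycardia events. Each
# channel is an AR(1) process around a clinical baseline; event patients get
# a linear pre-onset prodrome (HR drift up, RR up, SpO2 down, inflated HR
# variability) followed by a sustained heart-rate plateau that satisfies a
# tachycardia criterion by construction. Static profiles are drawn from the
# published cohort composition of the two care settings.

.static_presets <- list(
  icu = list(
    age_mean = 66, age_sd = 17.6,
    female = 0.572,
    admission = c(elective = 0.172, emergency = 0.798, urgent = 0.030),
    unit = c("coronary" = 0.209, "cardiac-surgery-recovery" = 0.196,
             "medical-ICU" = 0.263, "surgical-ICU" = 0.232,
             "trauma-surgical-ICU" = 0.100),
    cvd = 0.866),
  ward = list(
    age_mean = 61, age_sd = 10.7,
    female = 0.405,
    admission = c(elective = 0.876, emergency = 0.124, urgent = 0),
    unit = NULL,                       # general-ward patients have no ICU stay
    cvd = 0.903)
)

#' Synthetic-cohort parameters
#'
#' Defaults emulate a critical-care monitoring cohort: per-minute records of
#' 14-24 hours, baselines HR 75 (SD 8) bpm, RR 16 (SD 3) breaths/min, SpO2
#' 97 (SD 1.5) percent, strongly autocorrelated noise (AR(1) coefficient
#' 0.9 per channel, innovation variance scaled so the stationary SD matches
#' the stated SD), and static profiles drawn from the published composition
#' of the corresponding study cohort. \code{setting = "ward"} switches to
#' the general-ward composition and shorter records (4-12 hours).
#'
#' @param n_patients cohort size.
#' @param prevalence fraction of patients receiving a tachycardia event.
#' @param setting \code{"icu"} or \code{"ward"} static-profile preset.
#' @param span_min,span_max monitoring span bounds in minutes (defaults
#'   840-1440 for ICU, 240-720 for ward).
#' @param baseline_mean,baseline_sd named numeric (hr, rr, spo2) baselines.
#' @param ar_coef named AR(1) coefficients in [0, 1) per channel.
#' @param seed integer cohort seed; per-patient seeds are derived from it.
#' @return list of class \code{"cohort_params"}.
#' @export
cohort_params <- function(n_patients = 100, prevalence = 0.3,
                          setting = c("icu", "ward"),
                          span_min = NULL, span_max = NULL,
                          baseline_mean = c(hr = 75, rr = 16, spo2 = 97),
                          baseline_sd = c(hr = 8, rr = 3, spo2 = 1.5),
                          ar_coef = c(hr = 0.9, rr = 0.9, spo2 = 0.9),
                          seed = 1L) {
  setting <- match.arg(setting)
  if (is.null(span_min)) span_min <- if (setting == "icu") 840L else 240L
  if (is.null(span_max)) span_max <- if (setting == "icu") 1440L else 720L
  stopifnot(prevalence >= 0, prevalence <= 1, all(ar_coef >= 0),
            all(ar_coef < 1), span_min <= span_max, n_patients >= 1)
  structure(list(n_patients = as.integer(n_patients),
                 prevalence = prevalence, setting = setting,
                 span_min = as.integer(span_min),
                 span_max = as.integer(span_max),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 ar_coef = ar_coef, seed = as.integer(seed)),
            class = "cohort_params")
}

#' Pre-onset prodrome specification
#'
#' The injected, recoverable predictive signal: linear ramps over the
#' \code{lead} minutes before onset (heart rate drifts up by \code{hr_drift}
#' bpm, respiratory rate up by \code{rr_drift}, SpO2 down by
#' \code{spo2_dip}), HR noise inflated by \code{variance_inflation}, then a
#' heart-rate plateau at \code{plateau_hr} for \code{plateau_minutes} from
#' onset. The plateau satisfies the >100 bpm / 30 min criterion by
#' construction (values are floored just above threshold), and the ramp is
#' capped at 100 bpm so the event cannot begin before the injected onset.
#' The default 6-hour lead reflects how long before serious adverse events
#' vital-sign deterioration is typically observed.
#'
#' @param lead prodrome length in minutes before onset (default 360).
#' @param hr_drift,rr_drift heart-rate / respiratory-rate rise over the ramp.
#' @param spo2_dip SpO2 fall over the ramp (percentage points).
#' @param variance_inflation multiplicative factor on HR noise in the
#'   prodrome (default 1.5).
#' @param plateau_hr mean heart rate of the event plateau (default 115 bpm).
#' @param plateau_minutes plateau duration (default 45, >= 30 so the
#'   100-bpm criterion holds).
#' @return list of class \code{"prodrome_spec"}.
#' @export
prodrome_spec <- function(lead = 360, hr_drift = 15, rr_drift = 4,
                          spo2_dip = 3, variance_inflation = 1.5,
                          plateau_hr = 115, plateau_minutes = 45) {
  stopifnot(lead > 0, plateau_minutes >= 30 || plateau_hr > 150,
            variance_inflation > 0)
  structure(list(lead = as.integer(lead), hr_drift = hr_drift,
                 rr_drift = rr_drift, spo2_dip = spo2_dip,
                 variance_inflation = variance_inflation,
                 plateau_hr = plateau_hr,
                 plateau_minutes = as.integer(plateau_minutes)),
            class = "prodrome_spec")
}

# stationary AR(1) noise with marginal SD sd
.ar1_noise <- function(n, phi, sd) {
  if (sd == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - phi^2)
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) {
    eps <- stats::rnorm(n - 1, 0, innov_sd)
    for (t in 2:n) e[t] <- phi * e[t - 1] + eps[t - 1]
  }
  e
}

#' Draw a static profile from a care-setting preset
#'
#' Ages are normal draws (truncated above 18) around the setting's cohort
#' median; categorical fields follow the setting's published proportions.
#' Ward patients always have \code{first_care_unit = "none"}.
#'
#' @param params a \code{\link{cohort_params}} (for the setting preset).
#' @param seed optional integer seed; \code{NULL} uses the current RNG
#'   state.
#' @return a \code{\link{static_profile}}.
#' @export
sample_static_profile <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pr <- .static_presets[[params$setting]]
  repeat {
    age <- stats::rnorm(1, pr$age_mean, pr$age_sd)
    if (age > 18) break
  }
  gender <- if (stats::runif(1) < pr$female) "female" else "male"
  adm <- sample(names(pr$admission), 1, prob = pr$admission)
  unit <- if (is.null(pr$unit)) "none" else sample(names(pr$unit), 1, prob = pr$unit)
  cvd <- stats::runif(1) < pr$cvd
  static_profile(age, gender, adm, unit, cvd)
}

#' Generate one synthetic patient record
#'
#' AR(1) channels around the configured baselines; when a
#' \code{\link{prodrome_spec}} is given, adds the prodrome ramps over
#' \code{[onset - lead, onset)} and the heart-rate plateau from onset.
#' Channels are clipped to physiological ranges.
#'
#' @param params a \code{\link{cohort_params}}.
#' @param spec a \code{\link{prodrome_spec}}, or \code{NULL} for an
#'   event-free record.
#' @param seed integer seed for this patient.
#' @param patient_id identifier (default derived from the seed).
#' @param onset_minute event onset minute; \code{NULL} draws it uniformly
#'   from the feasible range \code{[lead + 120, span - plateau]}.
#' @return list: \code{record} (a \code{\link{patient_record}}) and
#'   \code{onset_minute} (\code{NA} for event-free records).
#' @export
generate_patient <- function(params, spec = NULL, seed = 1L,
                             patient_id = sprintf("P%06d", seed %% 1000000L),
                             onset_minute = NULL) {
  set.seed(seed)
  span <- sample(params$span_min:params$span_max, 1)
  profile <- sample_static_profile(params)

  mu <- params$baseline_mean; sd <- params$baseline_sd; phi <- params$ar_coef
  hr_noise <- .ar1_noise(span, phi["hr"], sd["hr"])
  hr <- mu["hr"] + hr_noise
  rr <- mu["rr"] + .ar1_noise(span, phi["rr"], sd["rr"])
  spo2 <- mu["spo2"] + .ar1_noise(span, phi["spo2"], sd["spo2"])
  onset <- NA_integer_

  if (!is.null(spec)) {
    lo <- spec$lead + 120L
    hi <- span - spec$plateau_minutes
    if (lo > hi) {
      stop("monitoring span too short to host the observing window, prodrome and event")
    }
    onset <- if (is.null(onset_minute)) sample(lo:hi, 1) else as.integer(onset_minute)
    if (onset < lo || onset > hi) stop("onset_minute outside the feasible range")
    ramp_idx <- (onset - spec$lead + 1L):onset          # R indices of [onset-lead, onset)
    frac <- seq_along(ramp_idx) / spec$lead
    hr[ramp_idx] <- mu["hr"] + spec$hr_drift * frac +
      hr_noise[ramp_idx] * spec$variance_inflation
    rr[ramp_idx] <- rr[ramp_idx] + spec$rr_drift * frac
    spo2[ramp_idx] <- spo2[ramp_idx] - spec$spo2_dip * frac
    # the event begins exactly at the injected onset: the ramp stays at or
    # below the lowest rule threshold, the plateau strictly above it
    hr[ramp_idx] <- pmin(hr[ramp_idx], 100)
    plat_idx <- (onset + 1L):(onset + spec$plateau_minutes)
    hr[plat_idx] <- pmax(spec$plateau_hr + hr_noise[plat_idx], 101)
    rr[plat_idx] <- rr[plat_idx] + spec$rr_drift
    spo2[plat_idx] <- spo2[plat_idx] - spec$spo2_dip
  }

  hr <- pmin(pmax(hr, 30), 300)
  rr <- pmin(pmax(rr, 4), 80)
  spo2 <- pmin(pmax(spo2, 50), 100)
  list(record = patient_record(patient_id, hr, rr, spo2, profile),
       onset_minute = onset)
}

#' Generate a reproducible synthetic cohort
#'
#' Exactly \code{round(prevalence * n)} patients receive a tachycardia
#' event. All randomness flows from the cohort seed through derived
#' per-patient seeds, so any patient can be regenerated individually from
#' the truth table.
#'
#' @param params a \code{\link{cohort_params}}.
#' @param prodrome a \code{\link{prodrome_spec}} applied to event patients.
#' @param seed cohort seed (defaults to \code{params$seed}).
#' @return list of class \code{"tachy_cohort"}: \code{records} (named list
#'   of patient records) and \code{truth} (data.frame: patient_id, event,
#'   onset_minute, prodrome_start, span, patient_seed).
#' @export
generate_cohort <- function(params, prodrome = prodrome_spec(),
                            seed = params$seed) {
  n <- params$n_patients
  set.seed(seed)
  patient_seeds <- sample.int(.Machine$integer.max - 1L, n)
  n_event <- round(params$prevalence * n)
  event <- logical(n)
  event[sample.int(n, n_event)] <- TRUE

  records <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- sprintf("P%04d", i)
    g <- generate_patient(params, if (event[i]) prodrome else NULL,
                          seed = patient_seeds[i], patient_id = pid)
    records[[i]] <- g$record
    truth[[i]] <- data.frame(
      patient_id = pid, event = event[i],
      onset_minute = g$onset_minute,
      prodrome_start = if (event[i]) g$onset_minute - prodrome$lead else NA_integer_,
      span = length(g$record$hr), patient_seed = patient_seeds[i],
      stringsAsFactors = FALSE)
  }
  names(records) <- vapply(records, `[[`, character(1), "patient_id")
  structure(list(records = records,
                 truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
                 params = params, prodrome = prodrome, seed = as.integer(seed)),
            class = "tachy_cohort")
}

#' @export
print.tachy_cohort <- function(x, ...) {
  cat(sprintf("<tachy_cohort> %d patients (%d with events), setting '%s', seed %d\n",
              length(x$records), sum(x$truth$event), x$params$setting, x$seed))
  invisible(x)
}

#' Write a cohort as plain-text CSV files
#'
#' Writes \code{vitals.csv} (patient_id, minute, hr, rr, spo2),
#' \code{static.csv}, and \code{truth.csv} under \code{dir}.
#'
#' @param cohort a \code{\link{generate_cohort}} result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vit <- do.call(rbind, lapply(cohort$records, function(r) {
    data.frame(patient_id = r$patient_id, minute = seq_along(r$hr) - 1L,
               hr = r$hr, rr = r$rr, spo2 = r$spo2)
  }))
  utils::write.csv(vit, file.path(dir, "vitals.csv"), row.names = FALSE)
  sta <- do.call(rbind, lapply(cohort$records, function(r) {
    p <- r$profile
    data.frame(patient_id = r$patient_id, age = p$age, gender = p$gender,
               admission_type = p$admission_type,
               first_care_unit = p$first_care_unit,
               cvd_history = p$cvd_history)
  }))
  utils::write.csv(sta, file.path(dir, "static.csv"), row.names = FALSE)
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
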