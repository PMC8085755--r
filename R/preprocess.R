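#' Downsample per-second vital-sign samples to a per-minute series
#'
#' Each minute's value is the arithmetic mean of that minute's valid samples,
#' where a sample is invalid if it is missing (\code{NA}) or exactly zero
#' (monitor drop-outs are recorded as 0 by most bedside systems). A minute in
#' which the invalid fraction exceeds \code{null_threshold} is emitted as
#' \code{NA} and left to \code{\link{fill_missing}}.
#'
#' @param values numeric vector of raw samples (typically per-second).
#' @param minute optional integer vector, same length as \code{values}, giving
#'   the minute index of each sample. When \code{NULL}, samples are grouped
#'   into consecutive blocks of \code{per}.
#' @param per samples per minute used when \code{minute} is \code{NULL}.
#' @param null_threshold maximum tolerated invalid fraction per minute
#'   (default 0.30; a minute with strictly more than this fraction of
#'   null/zero samples is treated as missing).
#' @return numeric per-minute vector, possibly containing \code{NA}.
#' @seealso \code{\link{fill_missing}}
#' @export
#' @examples
#' downsample_to_minute(rep(80, 60))                       # 80
#' downsample_to_minute(c(rep(0, 20), rep(90, 40)))        # NA: 33% invalid
downsample_to_minute <- function(values, minute = NULL, per = 60,
                                 null_threshold = 0.30) {
  if (length(values) == 0L) stop("no samples supplied")
  if (is.null(minute)) {
    minute <- (seq_along(values) - 1L) %/% as.integer(per)
  }
  if (length(minute) != length(values)) {
    stop("'minute' must align with 'values'")
  }
  groups <- split(values, minute)
  out <- vapply(groups, function(g) {
    bad <- is.na(g) | g == 0
    if (mean(bad) > null_threshold || all(bad)) return(NA_real_)
    mean(g[!bad])
  }, numeric(1))
  unname(out)
}

#' Fill missing per-minute values by carrying the last observation forward
#'
#' Causal filling: each missing minute takes the most recent preceding
#' observed value. Leading minutes with no predecessor are trimmed from the
#' start of the record (back-filling would leak future data into a real-time
#' predictor).
#'
#' @param x numeric per-minute series with \code{NA} marking missing minutes.
#' @return numeric series with no missing values; attribute \code{"trimmed"}
#'   records how many leading minutes were removed.
#' @export
#' @examples
#' fill_missing(c(80, NA, NA, 90))  # 80 80 80 90
#' fill_missing(c(NA, 70, 70))      # 70 70 (one leading minute trimmed)
fill_missing <- function(x) {
  if (length(x) == 0L) stop("empty series")
  first_obs <- which(!is.na(x))[1]
  if (is.na(first_obs)) stop("series is entirely missing; nothing to carry forward")
  trimmed <- first_obs - 1L
  x <- x[first_obs:length(x)]
  idx <- cumsum(!is.na(x))        # index of the latest observation at each minute
  out <- x[!is.na(x)][idx]
  attr(out, "trimmed") <- trimmed
  out
}

.vital_ranges <- list(hr = c(0, 300), rr = c(0, 80), spo2 = c(0, 100))

#' Static patient profile
#'
#' Demographic and admission attributes fused with the vital-sign features:
#' age in years, gender, hospital admission type, first critical-care unit
#' (\code{"none"} for general-ward patients, whose stay involves no ICU), and
#' history of cardiovascular disease.
#'
#' @param age years, numeric > 18.
#' @param gender \code{"female"} or \code{"male"}.
#' @param admission_type one of \code{"elective"}, \code{"emergency"},
#'   \code{"urgent"}.
#' @param first_care_unit one of \code{"coronary"},
#'   \code{"cardiac-surgery-recovery"}, \code{"medical-ICU"},
#'   \code{"surgical-ICU"}, \code{"trauma-surgical-ICU"}, \code{"none"}.
#' @param cvd_history logical, history of cardiovascular disease.
#' @return object of class \code{"static_profile"}.
#' @export
static_profile <- function(age, gender, admission_type,
                           first_care_unit = "none", cvd_history = FALSE) {
  stopifnot(is.numeric(age), length(age) == 1L, age > 18)
  gender <- match.arg(gender, c("female", "male"))
  admission_type <- match.arg(admission_type, c("elective", "emergency", "urgent"))
  first_care_unit <- match.arg(first_care_unit,
    c("coronary", "cardiac-surgery-recovery", "medical-ICU",
      "surgical-ICU", "trauma-surgical-ICU", "none"))
  structure(list(age = as.numeric(age), gender = gender,
                 admission_type = admission_type,
                 first_care_unit = first_care_unit,
                 cvd_history = isTRUE(cvd_history)),
            class = "static_profile")
}

#' Per-patient monitoring record
#'
#' Aligned, complete per-minute heart-rate, respiratory-rate and SpO2 series
#' on a shared minute grid (0-based from record start), plus the patient's
#' static profile. Construction validates physiological ranges and enforces
#' equal channel lengths and absence of missing values.
#'
#' @param patient_id opaque identifier.
#' @param hr,rr,spo2 complete per-minute numeric series of equal length
#'   (bpm, breaths/min, percent).
#' @param profile a \code{\link{static_profile}}.
#' @param start_minute integer offset of the first sample from admission.
#' @return object of class \code{"patient_record"}.
#' @export
patient_record <- function(patient_id, hr, rr, spo2, profile,
                           start_minute = 0L) {
  n <- length(hr)
  if (n == 0L) stop("record has no samples")
  if (length(rr) != n || length(spo2) != n) {
    stop("hr, rr and spo2 must share one minute grid")
  }
  chans <- list(hr = hr, rr = rr, spo2 = spo2)
  for (nm in names(chans)) {
    v <- chans[[nm]]
    if (anyNA(v)) stop("channel '", nm, "' still has missing values; run fill_missing() first")
    rng <- .vital_ranges[[nm]]
    if (any(v <= rng[1] | v > rng[2])) {
      stop("channel '", nm, "' outside physiological range (", rng[1], ", ", rng[2], "]")
    }
  }
  stopifnot(inherits(profile, "static_profile"))
  structure(list(patient_id = as.character(patient_id),
                 hr = as.numeric(hr), rr = as.numeric(rr),
                 spo2 = as.numeric(spo2),
                 profile = profile,
                 start_minute = as.integer(start_minute)),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat("<patient_record> id:", x$patient_id,
      " span:", length(x$hr), "min",
      " HR mean:", round(mean(x$hr), 1), "bpm\n")
  invisible(x)
}

#' @export
length.patient_record <- function(x) length(x$hr)

#' Read per-minute vitals from CSV
#'
#' Expected columns: \code{patient_id}, \code{minute} (integer, 0-based from
#' admission), \code{hr}, \code{rr}, \code{spo2}; an empty cell marks a
#' missing minute.
#'
#' @param path CSV file path.
#' @return data.frame with one row per (patient, minute).
#' @export
read_vitals_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "minute", "hr", "rr", "spo2")
  if (!all(need %in% names(df))) {
    stop("vitals CSV must have columns: ", paste(need, collapse = ", "))
  }
  df$patient_id <- as.character(df$patient_id)
  df
}

#' Read static patient profiles from CSV
#'
#' Expected columns: \code{patient_id}, \code{age}, \code{gender},
#' \code{admission_type}, \code{first_care_unit}, \code{cvd_history}.
#'
#' @param path CSV file path.
#' @return data.frame with one row per patient.
#' @export
read_static_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "age", "gender", "admission_type",
            "first_care_unit", "cvd_history")
  if (!all(need %in% names(df))) {
    stop("static CSV must have columns: ", paste(need, collapse = ", "))
  }
  df$patient_id <- as.character(df$patient_id)
  df
}

#' Assemble patient records from vitals and static tables
#'
#' Per patient: sorts by minute, forward-fills each channel, trims the record
#' start to the latest channel's first observation so all three channels are
#' complete on a shared grid.
#'
#' @param vitals data.frame as returned by \code{\link{read_vitals_csv}}.
#' @param static data.frame as returned by \code{\link{read_static_csv}}.
#' @return named list of \code{\link{patient_record}} objects.
#' @export
as_patient_records <- function(vitals, static) {
  static_by_id <- split(static, static$patient_id)
  out <- list()
  for (pid in unique(vitals$patient_id)) {
    sub <- vitals[vitals$patient_id == pid, , drop = FALSE]
    sub <- sub[order(sub$minute), , drop = FALSE]
    filled <- lapply(sub[c("hr", "rr", "spo2")], function(v) fill_missing(as.numeric(v)))
    trims <- vapply(filled, function(v) attr(v, "trimmed"), integer(1))
    lead <- max(trims)
    n <- min(vapply(filled, length, integer(1)) + trims) - lead
    aligned <- lapply(seq_along(filled), function(i) {
      v <- filled[[i]]
      v[(lead - trims[i] + 1L):(lead - trims[i] + n)]
    })
    srow <- static_by_id[[pid]]
    if (is.null(srow)) stop("no static profile for patient ", pid)
    prof <- static_profile(age = srow$age[1], gender = srow$gender[1],
                           admission_type = srow$admission_type[1],
                           first_care_unit = srow$first_care_unit[1],
                           cvd_history = as.logical(srow$cvd_history[1]))
    out[[pid]] <- patient_record(pid, aligned[[1]], aligned[[2]], aligned[[3]],
                                 prof, start_minute = sub$minute[1] + lead)
  }
  out
}
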