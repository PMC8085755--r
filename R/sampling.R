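#' Sample-extraction configuration
#'
#' Geometry and inclusion rules used to turn monitoring records into labeled
#' training windows: negatives are strided windows over tachycardia-free
#' records; positives are windows ending one forecast range before onset,
#' augmented ("target replication") by re-extracting windows shifted 5
#' minutes earlier.
#'
#' @param observing_window observing-window length in minutes (default 120).
#' @param neg_stride sliding step for negative windows in minutes (default 60).
#' @param forecast_range gap between window end and onset, in hours
#'   (0, 2, 4 or 6 in the standard experiments; any non-negative value works).
#' @param replication_step shift between replicated positive windows,
#'   minutes (default 5).
#' @param replication_count number of extra replicated positives per onset
#'   (default 4).
#' @param min_monitoring minimum record length in minutes for cohort
#'   inclusion (default 840, i.e. 14 h, the critical-care rule; general-ward
#'   cohorts relax this to 240).
#' @param min_age minimum age in years (default 18, exclusive).
#' @param seed integer seed for the balancing subsample and patient split.
#' @return list of class \code{"sampling_config"}.
#' @export
sampling_config <- function(observing_window = 120, neg_stride = 60,
                            forecast_range = 2, replication_step = 5,
                            replication_count = 4, min_monitoring = 840,
                            min_age = 18, seed = 1L) {
  stopifnot(forecast_range >= 0, replication_count >= 0, neg_stride >= 1)
  structure(list(observing_window = as.integer(observing_window),
                 neg_stride = as.integer(neg_stride),
                 forecast_range = as.numeric(forecast_range),
                 replication_step = as.integer(replication_step),
                 replication_count = as.integer(replication_count),
                 min_monitoring = as.integer(min_monitoring),
                 min_age = as.numeric(min_age),
                 seed = as.integer(seed)),
            class = "sampling_config")
}

#' Encode a static profile as a numeric covariate vector
#'
#' age (1) + gender indicator (1, male = 1) + admission-type indicators (3) +
#' first-care-unit indicators (5, all zero for general-ward patients with no
#' unit) + cardiovascular-history indicator (1) = 11 values. The vector is
#' appended to every time step of a window's feature sequence before the
#' sequence enters the classifier.
#'
#' @param profile a \code{\link{static_profile}}.
#' @return named numeric vector of length 11.
#' @export
encode_static <- function(profile) {
  stopifnot(inherits(profile, "static_profile"))
  adm <- c(elective = 0, emergency = 0, urgent = 0)
  adm[profile$admission_type] <- 1
  units <- c("coronary", "cardiac-surgery-recovery", "medical-ICU",
             "surgical-ICU", "trauma-surgical-ICU")
  unit <- stats::setNames(numeric(5), paste0("unit_", units))
  if (profile$first_care_unit != "none") {
    unit[paste0("unit_", profile$first_care_unit)] <- 1
  }
  c(age = profile$age,
    male = as.numeric(profile$gender == "male"),
    adm_elective = unname(adm["elective"]),
    adm_emergency = unname(adm["emergency"]),
    adm_urgent = unname(adm["urgent"]),
    unit,
    cvd_history = as.numeric(profile$cvd_history))
}

# Assemble a labeled_samples container from parallel per-sample pieces.
.new_samples <- function(feat_list, static_mat, label, patient_id,
                         window_end, forecast_range) {
  n <- length(feat_list)
  if (n == 0L) {
    return(structure(list(features = NULL, static = NULL, label = integer(0),
                          patient_id = character(0), window_end = integer(0),
                          forecast_range = numeric(0)),
                     class = "labeled_samples"))
  }
  T <- nrow(feat_list[[1]]); P <- ncol(feat_list[[1]])
  arr <- array(NA_real_, c(n, T, P),
               dimnames = list(NULL, NULL, colnames(feat_list[[1]])))
  for (i in seq_len(n)) arr[i, , ] <- feat_list[[i]]
  structure(list(features = arr, static = static_mat,
                 label = as.integer(label),
                 patient_id = as.character(patient_id),
                 window_end = as.integer(window_end),
                 forecast_range = as.numeric(forecast_range)),
            class = "labeled_samples")
}

#' @export
length.labeled_samples <- function(x) length(x$label)

#' @export
print.labeled_samples <- function(x, ...) {
  cat(sprintf("<labeled_samples> n=%d (%d positive / %d negative), %d patients\n",
              length(x$label), sum(x$label == 1L), sum(x$label == 0L),
              length(unique(x$patient_id))))
  invisible(x)
}

#' Combine labeled sample sets
#' @param ... \code{labeled_samples} objects.
#' @return one \code{labeled_samples} object.
#' @export
combine_samples <- function(...) {
  parts <- Filter(function(s) length(s$label) > 0, list(...))
  if (length(parts) == 0L) return(.new_samples(list(), NULL, integer(0),
                                               character(0), integer(0), numeric(0)))
  feats <- do.call(abind_first, lapply(parts, `[[`, "features"))
  structure(list(features = feats,
                 static = do.call(rbind, lapply(parts, `[[`, "static")),
                 label = unlist(lapply(parts, `[[`, "label")),
                 patient_id = unlist(lapply(parts, `[[`, "patient_id")),
                 window_end = unlist(lapply(parts, `[[`, "window_end")),
                 forecast_range = unlist(lapply(parts, `[[`, "forecast_range"))),
            class = "labeled_samples")
}

# bind 3D arrays along the first (sample) dimension
abind_first <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  n <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  out <- array(NA_real_, c(n, d[2], d[3]), dimnames = list(NULL, NULL, dimnames(arrs[[1]])[[3]]))
  at <- 0L
  for (a in arrs) {
    k <- dim(a)[1]
    out[at + seq_len(k), , ] <- a
    at <- at + k
  }
  out
}

# subset a labeled_samples object by index vector
subset_samples <- function(s, idx) {
  structure(list(features = s$features[idx, , , drop = FALSE],
                 static = s$static[idx, , drop = FALSE],
                 label = s$label[idx], patient_id = s$patient_id[idx],
                 window_end = s$window_end[idx],
                 forecast_range = s$forecast_range[idx]),
            class = "labeled_samples")
}

#' Extract negative (tachycardia-free) samples from one record
#'
#' Windows ending at \code{observing_window}, then every \code{neg_stride}
#' minutes, across the whole record; only records with no detected onset are
#' eligible.
#'
#' @param record a \code{\link{patient_record}} with no tachycardia onset.
#' @param config a \code{\link{sampling_config}}.
#' @param geometry,registry window geometry and feature registry.
#' @param criteria onset rule set used to enforce the no-event precondition.
#' @return a \code{labeled_samples} object (possibly empty).
#' @export
extract_negatives <- function(record, config = sampling_config(),
                              geometry = window_geometry(),
                              registry = feature_registry(),
                              criteria = tachy_criteria()) {
  if (!is.null(detect_onset(record$hr, criteria))) {
    stop("record ", record$patient_id,
         " has a tachycardia onset; negatives come only from event-free records")
  }
  L <- length(record$hr)
  ow <- config$observing_window
  if (L < ow) return(.new_samples(list(), NULL, integer(0), character(0),
                                  integer(0), numeric(0)))
  ends <- seq(ow, L, by = config$neg_stride)
  sv <- encode_static(record$profile)
  feats <- lapply(ends, function(e) extract_sequence(record, e, geometry, registry))
  .new_samples(feats, matrix(sv, nrow = length(ends), ncol = length(sv),
                             byrow = TRUE, dimnames = list(NULL, names(sv))),
               rep(0L, length(ends)), rep(record$patient_id, length(ends)),
               ends, rep(config$forecast_range, length(ends)))
}

#' Extract positive (pre-onset) samples from one record
#'
#' The base window ends one forecast range before onset; replication
#' \code{r = 1..replication_count} adds windows ending \code{5 r} minutes
#' earlier still, each kept only if the record covers its full observing
#' window.
#'
#' @param record a \code{\link{patient_record}}.
#' @param onset an \code{onset_event} for the record (or \code{NULL} to
#'   detect it here).
#' @param config a \code{\link{sampling_config}}.
#' @param geometry,registry window geometry and feature registry.
#' @return a \code{labeled_samples} object (empty when there is not enough
#'   pre-onset history).
#' @export
extract_positives <- function(record, onset = NULL,
                              config = sampling_config(),
                              geometry = window_geometry(),
                              registry = feature_registry()) {
  if (is.null(onset)) onset <- detect_onset(record$hr)
  if (is.null(onset)) stop("record has no tachycardia onset")
  ow <- config$observing_window
  fr_min <- round(config$forecast_range * 60)
  base_end <- onset$onset_minute - fr_min
  ends <- base_end - config$replication_step * (0:config$replication_count)
  ends <- ends[ends >= ow & ends <= length(record$hr)]
  if (length(ends) == 0L) {
    return(.new_samples(list(), NULL, integer(0), character(0),
                        integer(0), numeric(0)))
  }
  sv <- encode_static(record$profile)
  feats <- lapply(ends, function(e) extract_sequence(record, e, geometry, registry))
  .new_samples(feats, matrix(sv, nrow = length(ends), ncol = length(sv),
                             byrow = TRUE, dimnames = list(NULL, names(sv))),
               rep(1L, length(ends)), rep(record$patient_id, length(ends)),
               ends, rep(config$forecast_range, length(ends)))
}

#' Build the labeled sample set for a cohort
#'
#' Applies the inclusion filters (age, minimum monitoring duration), labels
#' each record, and extracts positives from event records and negatives from
#' event-free records.
#'
#' @param records list of \code{\link{patient_record}} objects.
#' @param config a \code{\link{sampling_config}}.
#' @param geometry,registry window geometry and feature registry.
#' @param criteria onset rule set.
#' @return a \code{labeled_samples} object.
#' @export
build_samples <- function(records, config = sampling_config(),
                          geometry = window_geometry(),
                          registry = feature_registry(),
                          criteria = tachy_criteria()) {
  parts <- list()
  for (rec in records) {
    if (rec$profile$age <= config$min_age) next
    if (length(rec$hr) < config$min_monitoring) next
    ev <- detect_onset(rec$hr, criteria)
    parts[[length(parts) + 1L]] <-
      if (is.null(ev)) extract_negatives(rec, config, geometry, registry, criteria)
      else extract_positives(rec, ev, config, geometry, registry)
  }
  do.call(combine_samples, parts)
}

#' Balance classes and split by patient
#'
#' Negatives are subsampled without replacement (seeded) down to the positive
#' count, then patients are randomly assigned to train or test, all of a
#' patient's samples on one side, targeting the requested patient fraction.
#'
#' @param samples a \code{labeled_samples} object with both classes present.
#' @param seed integer seed.
#' @param train_frac fraction of patients assigned to training (default 0.8).
#' @return list with \code{train} and \code{test} \code{labeled_samples}.
#' @export
balance_and_split <- function(samples, seed = 1L, train_frac = 0.8) {
  n_pos <- sum(samples$label == 1L)
  n_neg <- sum(samples$label == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  set.seed(seed)
  keep_neg <- which(samples$label == 0L)
  if (n_neg > n_pos) keep_neg <- sort(sample(keep_neg, n_pos))
  keep <- sort(c(which(samples$label == 1L), keep_neg))
  bal <- subset_samples(samples, keep)

  patients <- sort(unique(bal$patient_id))
  n_train <- round(train_frac * length(patients))
  train_pat <- sample(patients, n_train)
  in_train <- bal$patient_id %in% train_pat
  list(train = subset_samples(bal, which(in_train)),
       test = subset_samples(bal, which(!in_train)))
}
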