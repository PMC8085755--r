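#' Tachycardia diagnostic criteria
#'
#' Clinical rule set for labeling tachycardia onset from a per-minute heart
#' rate: an event is any maximal run of minutes with heart rate strictly above
#' a threshold whose length reaches the minimum sustained duration. The
#' defaults are the consensus rules (>100 bpm for >=30 min, >130 for >=20,
#' >150 for >=5).
#'
#' @param hr_threshold numeric vector of thresholds in bpm.
#' @param min_duration integer vector of minimum run lengths in minutes,
#'   aligned with \code{hr_threshold}.
#' @return data.frame of class \code{"tachy_criteria"}.
#' @export
tachy_criteria <- function(hr_threshold = c(100, 130, 150),
                           min_duration = c(30, 20, 5)) {
  stopifnot(length(hr_threshold) == length(min_duration),
            length(hr_threshold) >= 1L,
            all(hr_threshold > 0), all(min_duration >= 1))
  structure(data.frame(hr_threshold = as.numeric(hr_threshold),
                       min_duration = as.integer(min_duration)),
            class = c("tachy_criteria", "data.frame"))
}

#' Detect tachycardia onset in a per-minute heart-rate series
#'
#' Scans maximal runs of minutes with heart rate strictly above each
#' criterion's threshold. A run qualifies when its length reaches the
#' criterion's minimum duration; the event returned is the one whose
#' qualifying run starts earliest (minute indices 0-based from record start),
#' ties broken in favor of the higher threshold. Only the first onset is the
#' record label; later qualifying runs are available via \code{all_events}
#' for simulator bookkeeping.
#'
#' @param hr complete per-minute heart-rate series (no \code{NA}), or a
#'   \code{\link{patient_record}}.
#' @param criteria a \code{\link{tachy_criteria}} rule set.
#' @param all_events if \code{TRUE}, return the list of all detected events
#'   in onset order instead of just the first.
#' @return an \code{onset_event} (list with \code{onset_minute},
#'   \code{hr_threshold}, \code{min_duration}, \code{run_length}), a list of
#'   them when \code{all_events}, or \code{NULL} if no run qualifies.
#' @export
#' @examples
#' hr <- rep(80, 840); hr[676:726] <- 110   # minutes 675..725, 0-based
#' detect_onset(hr)$onset_minute            # 675
detect_onset <- function(hr, criteria = tachy_criteria(), all_events = FALSE) {
  if (inherits(hr, "patient_record")) hr <- hr$hr
  if (length(hr) == 0L) stop("empty heart-rate series")
  if (anyNA(hr)) stop("heart-rate series must be complete")

  events <- list()
  for (j in seq_len(nrow(criteria))) {
    thr <- criteria$hr_threshold[j]
    dur <- criteria$min_duration[j]
    r <- rle(hr > thr)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- r$values & r$lengths >= dur
    for (i in which(ok)) {
      events[[length(events) + 1L]] <- structure(
        list(onset_minute = starts[i] - 1L,   # 0-based
             hr_threshold = thr, min_duration = dur,
             run_length = r$lengths[i]),
        class = "onset_event")
    }
  }
  if (length(events) == 0L) return(NULL)
  onset <- vapply(events, `[[`, numeric(1), "onset_minute")
  thr <- vapply(events, `[[`, numeric(1), "hr_threshold")
  ord <- order(onset, -thr)
  events <- events[ord]
  if (all_events) events else events[[1]]
}

#' @export
print.onset_event <- function(x, ...) {
  cat(sprintf("<onset_event> minute %d (rule >%g bpm / >=%d min, run %d min)\n",
              x$onset_minute, x$hr_threshold, x$min_duration, x$run_length))
  invisible(x)
}

#' Label onsets across a cohort
#'
#' @param records list of \code{\link{patient_record}} objects.
#' @param criteria a \code{\link{tachy_criteria}} rule set.
#' @return data.frame with one row per patient: \code{patient_id},
#'   \code{onset_minute} (\code{NA} if none), \code{hr_threshold},
#'   \code{min_duration}, \code{run_length}.
#' @export
label_onsets <- function(records, criteria = tachy_criteria()) {
  rows <- lapply(records, function(rec) {
    ev <- detect_onset(rec$hr, criteria)
    data.frame(patient_id = rec$patient_id,
               onset_minute = if (is.null(ev)) NA_integer_ else ev$onset_minute,
               hr_threshold = if (is.null(ev)) NA_real_ else ev$hr_threshold,
               min_duration = if (is.null(ev)) NA_integer_ else ev$min_duration,
               run_length = if (is.null(ev)) NA_integer_ else ev$run_length,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
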