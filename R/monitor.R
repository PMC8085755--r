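#' Real-time monitoring configuration
#'
#' @param evaluation_step minutes between risk evaluations (default 5).
#' @param threshold alarm threshold on the risk score (default 0.40).
#' @param persistence number of consecutive evaluations above threshold
#'   required before alarming (default 1).
#' @return list of class \code{"monitor_config"}.
#' @export
monitor_config <- function(evaluation_step = 5, threshold = 0.40,
                           persistence = 1) {
  stopifnot(threshold > 0, threshold < 1, persistence >= 1,
            evaluation_step >= 1)
  structure(list(evaluation_step = as.integer(evaluation_step),
                 threshold = as.numeric(threshold),
                 persistence = as.integer(persistence)),
            class = "monitor_config")
}

#' Stream risk scores over a monitoring record
#'
#' Evaluates the model on the trailing observing window every
#' \code{evaluation_step} minutes, starting as soon as a full window is
#' available (minute 120 with the default geometry). Strictly causal: the
#' score at minute t uses only minutes < t.
#'
#' @param record a \code{\link{patient_record}}.
#' @param model a fitted \code{\link{tachynet}} model.
#' @param config a \code{\link{monitor_config}}.
#' @param geometry,registry window geometry and feature registry (must match
#'   the model's training featurization).
#' @return data.frame with columns \code{minute} and \code{score}; empty if
#'   the record is shorter than one observing window.
#' @export
stream_scores <- function(record, model, config = monitor_config(),
                          geometry = window_geometry(),
                          registry = feature_registry()) {
  L <- length(record$hr)
  ow <- geometry$observing_window
  if (L < ow) return(data.frame(minute = integer(0), score = numeric(0)))
  evals <- seq(ow, L, by = config$evaluation_step)
  sv <- encode_static(record$profile)
  feats <- lapply(evals, function(e) extract_sequence(record, e, geometry, registry))
  batch <- .new_samples(feats,
                        matrix(sv, nrow = length(evals), ncol = length(sv),
                               byrow = TRUE, dimnames = list(NULL, names(sv))),
                        rep(NA_integer_, length(evals)),
                        rep(record$patient_id, length(evals)), evals,
                        rep(NA_real_, length(evals)))
  data.frame(minute = evals, score = predict(model, batch))
}

#' Raise a persistence-gated alarm from a score stream
#'
#' Scans the time-ordered evaluations for runs of consecutive scores
#' strictly above the threshold; the alarm fires at the evaluation where a
#' run first reaches \code{persistence} exceedances (with the default
#' persistence 1, the first exceedance itself).
#'
#' @param scores data.frame with \code{minute} and \code{score}
#'   (time-ordered), as from \code{\link{stream_scores}}.
#' @param config a \code{\link{monitor_config}}.
#' @return list of class \code{"alarm_result"}: \code{alarm_minute}
#'   (\code{NA} if never), the score series, threshold and persistence.
#' @export
raise_alarm <- function(scores, config = monitor_config()) {
  exceed <- scores$score > config$threshold
  run <- 0L
  alarm <- NA_integer_
  for (i in seq_along(exceed)) {
    run <- if (exceed[i]) run + 1L else 0L
    if (run == config$persistence) { alarm <- scores$minute[i]; break }
  }
  structure(list(alarm_minute = alarm, scores = scores,
                 threshold = config$threshold,
                 persistence = config$persistence),
            class = "alarm_result")
}

#' @export
print.alarm_result <- function(x, ...) {
  if (is.na(x$alarm_minute)) {
    cat(sprintf("<alarm_result> no alarm (threshold %.2f, persistence %d)\n",
                x$threshold, x$persistence))
  } else {
    cat(sprintf("<alarm_result> alarm at minute %d (threshold %.2f, persistence %d)\n",
                x$alarm_minute, x$threshold, x$persistence))
  }
  invisible(x)
}

#' Lead time between an alarm and the subsequent onset
#'
#' @param alarm_minute alarm minute, or \code{NA} for a missed event.
#' @param onset_minute tachycardia onset minute.
#' @return list: \code{minutes} (onset - alarm; 0 when the alarm came late;
#'   \code{NA} when missed) and \code{status} in \code{"ok"}, \code{"late"},
#'   \code{"missed"}.
#' @export
lead_time <- function(alarm_minute, onset_minute) {
  if (is.na(alarm_minute)) {
    return(list(minutes = NA_real_, status = "missed"))
  }
  if (alarm_minute > onset_minute) {
    return(list(minutes = 0, status = "late"))
  }
  list(minutes = as.numeric(onset_minute - alarm_minute), status = "ok")
}

#' Plot a monitored record: heart rate and streamed risk score
#'
#' Two stacked panels: the per-minute heart rate with the detected onset
#' marked, and the risk-score stream with the alarm threshold and alarm
#' minute.
#'
#' @param record a \code{\link{patient_record}}.
#' @param scores score stream from \code{\link{stream_scores}}.
#' @param alarm optional \code{alarm_result}.
#' @param onset optional onset minute to mark.
#' @return invisibly, \code{NULL}.
#' @export
plot_monitoring <- function(record, scores, alarm = NULL, onset = NULL) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(record$hr) - 1L, record$hr, type = "l",
                 xlab = "minute", ylab = "heart rate (bpm)")
  graphics::abline(h = 100, lty = 3)
  if (!is.null(onset)) graphics::abline(v = onset, col = 2, lty = 2)
  graphics::plot(scores$minute, scores$score, type = "l", ylim = c(0, 1),
                 xlab = "minute", ylab = "risk score")
  if (!is.null(alarm)) {
    graphics::abline(h = alarm$threshold, lty = 3)
    if (!is.na(alarm$alarm_minute)) {
      graphics::abline(v = alarm$alarm_minute, col = 4, lty = 2)
    }
  }
  invisible(NULL)
}
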