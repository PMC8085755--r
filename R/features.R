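#' Absolute energy of a time series
#'
#' Sum of squared sample values, a magnitude-sensitive summary of a window.
#'
#' @param x numeric series, length >= 1.
#' @return scalar \eqn{\sum_i X_i^2}.
#' @export
#' @examples abs_energy(1:3)  # 14
abs_energy <- function(x) {
  if (length(x) == 0L) stop("empty series")
  sum(x^2)
}

#' Lagged autocorrelation of a time series
#'
#' Normalized lag-\code{l} autocovariance
#' \deqn{R(l) = \frac{1}{(n-l)\,\sigma^2} \sum_{i=1}^{n-l} (X_i-\mu)(X_{i+l}-\mu)}
#' with \eqn{\mu} the series mean and \eqn{\sigma^2} the population variance.
#' A constant series (\eqn{\sigma^2 = 0}) returns 0 by convention.
#'
#' @param x numeric series of length \code{n}.
#' @param l positive integer lag, \code{l < n}.
#' @return scalar similarity of the series with its lag-\code{l} shift.
#' @export
autocorrelation <- function(x, l) {
  n <- length(x)
  l <- as.integer(l)
  if (l < 1L) stop("lag must be a positive integer")
  if (l >= n) stop("lag must be smaller than the series length")
  mu <- mean(x)
  sigma2 <- mean((x - mu)^2)        # population variance
  if (sigma2 == 0) return(0)
  sum((x[1:(n - l)] - mu) * (x[(1 + l):n] - mu)) / ((n - l) * sigma2)
}

#' Third-order nonlinearity statistic (c3)
#'
#' Mean lagged triple product
#' \deqn{c_3(lag) = \frac{1}{n-2\,lag} \sum_{i=1}^{n-2\,lag}
#'   X_{i+2\,lag}\, X_{i+lag}\, X_i,}
#' a measure of nonlinearity / time-irreversibility of the window.
#'
#' @param x numeric series of length \code{n > 2*lag}.
#' @param lag positive integer time delay.
#' @return scalar c3 value.
#' @export
#' @examples c3(1:6, 1)  # 52.5
c3 <- function(x, lag) {
  n <- length(x)
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be a positive integer")
  if (n <= 2L * lag) stop("series too short: need length > 2*lag")
  m <- n - 2L * lag
  idx <- seq_len(m)
  sum(x[idx + 2L * lag] * x[idx + lag] * x[idx]) / m
}

#' Least-squares trend slope of a window
#'
#' Slope of the ordinary least-squares line of the values against the sample
#' index, in value units per minute for a per-minute window.
#'
#' @param x numeric series, length >= 2.
#' @return scalar slope.
#' @export
ts_slope <- function(x) {
  n <- length(x)
  if (n < 2L) stop("need at least two samples for a slope")
  t <- seq_len(n)
  tc <- t - mean(t)
  sum(tc * x) / sum(tc^2)
}

#' Default statistical-feature registry
#'
#' The 21-feature catalogue computed per 20-minute sub-window, in fixed order:
#' 10 heart-rate features (mean, SD, sum, slope, absolute energy, c3 at lags
#' 2 and 3, quantiles 0.1/0.3/0.7), 5 respiratory-rate and 5 SpO2 features
#' (mean, SD, slope, absolute energy / c3 at lag 3), and one joint feature,
#' \code{all_autocorrelation}: the lag-40 autocorrelation averaged over the
#' three channels, computed over the full observing window (the default lag
#' 40 exceeds a 20-sample sub-window) and replicated at every time step.
#' \code{hr_c2} is the c3 statistic at lag 2 — the historical name is kept.
#'
#' Feature subsets for ablation configurations are selected with
#' \code{channels}; the joint autocorrelation feature requires all three.
#'
#' @param channels which vital signs to include; the default full set yields
#'   21 features, \code{"hr"} alone 10, \code{"hr"}+one other 15.
#' @return data.frame with columns \code{name}, \code{channel},
#'   \code{stat}, \code{param}, in canonical row order.
#' @export
feature_registry <- function(channels = c("hr", "rr", "spo2")) {
  channels <- match.arg(channels, c("hr", "rr", "spo2"), several.ok = TRUE)
  reg <- rbind(
    data.frame(name = c("hr_mean", "hr_std", "hr_sum", "hr_slope",
                        "hr_abs_energy", "hr_c2", "hr_c3",
                        "hr_quantiles_01", "hr_quantiles_03", "hr_quantiles_07"),
               channel = "hr",
               stat = c("mean", "std", "sum", "slope", "abs_energy",
                        "c3", "c3", "quantile", "quantile", "quantile"),
               param = c(NA, NA, NA, NA, NA, 2, 3, 0.1, 0.3, 0.7)),
    data.frame(name = c("resp_mean", "resp_std", "resp_slope",
                        "resp_abs_energy", "resp_c3"),
               channel = "rr",
               stat = c("mean", "std", "slope", "abs_energy", "c3"),
               param = c(NA, NA, NA, NA, 3)),
    data.frame(name = c("spo2_mean", "spo2_std", "spo2_slope",
                        "spo2_c3", "spo2_abs_energy"),
               channel = "spo2",
               stat = c("mean", "std", "slope", "c3", "abs_energy"),
               param = c(NA, NA, NA, 3, NA)),
    data.frame(name = "all_autocorrelation", channel = "all",
               stat = "autocorr_agg", param = 40)
  )
  keep <- reg$channel %in% channels |
    (reg$channel == "all" & length(channels) == 3L)
  out <- reg[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.apply_stat <- function(stat, x, param) {
  switch(stat,
         mean = mean(x),
         std = stats::sd(x),
         sum = sum(x),
         slope = ts_slope(x),
         abs_energy = abs_energy(x),
         c3 = c3(x, param),
         quantile = unname(stats::quantile(x, param, type = 7)),
         stop("unknown stat: ", stat))
}

#' Feature vector for one sub-observing window
#'
#' Evaluates every registry feature on the aligned 20-minute channel slices.
#' The joint autocorrelation feature is supplied by the caller because its
#' lag spans the whole observing window (see \code{\link{extract_sequence}}).
#'
#' @param hr,rr,spo2 aligned complete channel slices for the sub-window.
#' @param registry a \code{\link{feature_registry}} table.
#' @param all_autocorr precomputed observing-window joint autocorrelation
#'   (required when the registry contains \code{all_autocorrelation}).
#' @return named numeric vector in registry order.
#' @export
extract_feature_vector <- function(hr, rr, spo2,
                                   registry = feature_registry(),
                                   all_autocorr = NULL) {
  chans <- list(hr = hr, rr = rr, spo2 = spo2)
  if (any(vapply(chans, anyNA, logical(1)))) stop("incomplete window")
  out <- numeric(nrow(registry))
  for (i in seq_len(nrow(registry))) {
    ch <- registry$channel[i]
    if (ch == "all") {
      if (is.null(all_autocorr)) stop("all_autocorrelation must be supplied")
      out[i] <- all_autocorr
    } else {
      out[i] <- .apply_stat(registry$stat[i], chans[[ch]], registry$param[i])
    }
  }
  names(out) <- registry$name
  out
}

#' Sub-window geometry of an observing window
#'
#' @param observing_window trailing window length in minutes (default 120).
#' @param sub_window sub-observing window length in minutes (default 20).
#' @param step sliding step between sub-windows in minutes (default 5).
#' @param autocorr_lag lag of the joint autocorrelation feature (default 40).
#' @return list of class \code{"window_geometry"}.
#' @export
window_geometry <- function(observing_window = 120, sub_window = 20,
                            step = 5, autocorr_lag = 40) {
  stopifnot(sub_window <= observing_window, step >= 1,
            (observing_window - sub_window) %% step == 0)
  structure(list(observing_window = as.integer(observing_window),
                 sub_window = as.integer(sub_window),
                 step = as.integer(step),
                 autocorr_lag = as.integer(autocorr_lag)),
            class = "window_geometry")
}

#' Feature sequence for one observing window
#'
#' Slices the trailing observing window ending at \code{window_end} (window
#' minutes are half-open: \code{[window_end - observing_window, window_end)},
#' 0-based from record start) into overlapping sub-windows and evaluates the
#' feature registry on each, concatenating the vectors along time. With the
#' default geometry this yields (120-20)/5 + 1 = 21 time steps. The joint
#' lag-40 autocorrelation is computed once per observing window — the mean of
#' \code{\link{autocorrelation}} at the registry lag across the three
#' channels over the full window — and replicated at every step.
#'
#' @param record a \code{\link{patient_record}}.
#' @param window_end window end minute (exclusive), 0-based from record
#'   start; the record must cover the full observing window.
#' @param geometry a \code{\link{window_geometry}}.
#' @param registry a \code{\link{feature_registry}} table.
#' @return numeric matrix, time steps x features, with feature names as
#'   column names; attribute \code{"window_end"}.
#' @export
extract_sequence <- function(record, window_end,
                             geometry = window_geometry(),
                             registry = feature_registry()) {
  ow <- geometry$observing_window
  if (window_end < ow || window_end > length(record$hr)) {
    stop("record does not cover the observing window ending at ", window_end)
  }
  w0 <- window_end - ow                    # 0-based start minute
  idx <- (w0 + 1L):window_end              # R indices of the observing window
  hr <- record$hr[idx]; rr <- record$rr[idx]; spo2 <- record$spo2[idx]

  joint <- NULL
  if (any(registry$channel == "all")) {
    l <- geometry$autocorr_lag
    joint <- mean(c(autocorrelation(hr, l), autocorrelation(rr, l),
                    autocorrelation(spo2, l)))
  }
  starts <- seq(0L, ow - geometry$sub_window, by = geometry$step)
  rows <- lapply(starts, function(s) {
    sl <- (s + 1L):(s + geometry$sub_window)
    extract_feature_vector(hr[sl], rr[sl], spo2[sl], registry, joint)
  })
  out <- do.call(rbind, rows)
  attr(out, "window_end") <- as.integer(window_end)
  out
}
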