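# Shared fixtures and independent naive-loop oracles used across tests.

icu_profile <- function() {
  static_profile(60, "male", "emergency", "medical-ICU", TRUE)
}

ward_profile <- function() {
  static_profile(55, "female", "elective", "none", TRUE)
}

const_record <- function(L, hr = 80, rr = 16, spo2 = 97, id = "X",
                         profile = icu_profile()) {
  patient_record(id, rep(hr, L), rep(rr, L), rep(spo2, L), profile)
}

# heart rate 80 except `level` over minutes [from, to] (0-based, inclusive)
plateau_hr <- function(L, from, to, level, base = 80) {
  hr <- rep(base, L)
  hr[(from + 1):(to + 1)] <- level
  hr
}

# small synthetic two-class sample set with a mean shift on every feature
toy_samples <- function(n = 40, T = 6, P = 4, sep = 2, seed = 1,
                        n_patients = max(4, n %/% 4)) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  feats <- array(stats::rnorm(n * T * P), c(n, T, P),
                 dimnames = list(NULL, NULL, paste0("f", seq_len(P))))
  feats[y == 1, , ] <- feats[y == 1, , ] + sep
  sv <- encode_static(icu_profile())
  static <- matrix(sv, n, length(sv), byrow = TRUE,
                   dimnames = list(NULL, names(sv)))
  static[, "age"] <- static[, "age"] + stats::rnorm(n, 0, 5)
  structure(list(features = feats, static = static, label = as.integer(y),
                 patient_id = sprintf("T%02d", 1L + ((seq_len(n) - 1L) *
                                                       n_patients) %/% n),
                 window_end = rep(120L, n), forecast_range = rep(2, n)),
            class = "labeled_samples")
}

# ---- independent oracles ---------------------------------------------------

oracle_onset <- function(hr, criteria = tachy_criteria()) {
  best <- NULL
  n <- length(hr)
  for (j in seq_len(nrow(criteria))) {
    thr <- criteria$hr_threshold[j]
    dur <- criteria$min_duration[j]
    if (dur > n) next
    for (s in seq_len(n - dur + 1)) {
      ok <- TRUE
      for (t in s:(s + dur - 1)) if (!(hr[t] > thr)) { ok <- FALSE; break }
      if (ok) {
        cand <- list(onset = s - 1L, thr = thr)
        if (is.null(best) || cand$onset < best$onset ||
            (cand$onset == best$onset && cand$thr > best$thr)) best <- cand
        break   # earliest window start for this criterion found
      }
    }
  }
  best
}

oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

oracle_autocorr <- function(x, l) {
  n <- length(x)
  mu <- 0; for (v in x) mu <- mu + v; mu <- mu / n
  s2 <- 0; for (v in x) s2 <- s2 + (v - mu)^2; s2 <- s2 / n
  if (s2 == 0) return(0)
  acc <- 0
  for (i in 1:(n - l)) acc <- acc + (x[i] - mu) * (x[i + l] - mu)
  acc / ((n - l) * s2)
}

oracle_c3 <- function(x, lag) {
  n <- length(x); m <- n - 2 * lag
  acc <- 0
  for (i in 1:m) acc <- acc + x[i + 2 * lag] * x[i + lag] * x[i]
  acc / m
}

oracle_slope <- function(x) {
  n <- length(x)
  sx <- sum(1:n); sy <- sum(x)
  sxx <- sum((1:n)^2); sxy <- sum((1:n) * x)
  (n * sxy - sx * sy) / (n * sxx - sx^2)
}

oracle_quantile <- function(x, p) {
  # linear interpolation between order statistics
  xs <- sort(x); n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  xs[lo] + (h - floor(h)) * (xs[hi] - xs[lo])
}

oracle_feature_vector <- function(hr, rr, spo2, joint) {
  std <- function(x) sqrt(sum((x - mean(x))^2) / (length(x) - 1))
  c(mean(hr), std(hr), sum(hr), oracle_slope(hr), sum(hr^2),
    oracle_c3(hr, 2), oracle_c3(hr, 3),
    oracle_quantile(hr, 0.1), oracle_quantile(hr, 0.3), oracle_quantile(hr, 0.7),
    mean(rr), std(rr), oracle_slope(rr), sum(rr^2), oracle_c3(rr, 3),
    mean(spo2), std(spo2), oracle_slope(spo2), oracle_c3(spo2, 3), sum(spo2^2),
    joint)
}
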