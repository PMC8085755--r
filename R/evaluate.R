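#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator: the probability that a randomly
#' chosen positive outscores a randomly chosen negative, ties counted one
#' half. Equivalent to the trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 (or logical) class labels; both classes required.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold classification metrics
#'
#' Confusion-table metrics at the rule \code{score > threshold}: sensitivity
#' (recall), specificity, accuracy, precision, and F1. When no sample is
#' predicted positive, precision (and hence F1) is reported as 0 and the
#' report is flagged.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 class labels; both classes required.
#' @param threshold decision threshold (default 0.5).
#' @return list of class \code{"metric_report"} with the five metrics, the
#'   confusion counts, \code{decision_threshold}, and
#'   \code{precision_undefined} flag.
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  fp <- sum(pred == 1L & labels == 0L)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  acc <- (tp + tn) / length(labels)
  undef <- (tp + fp) == 0L
  prec <- if (undef) 0 else tp / (tp + fp)
  f1 <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
  structure(list(sensitivity = sens, specificity = spec, accuracy = acc,
                 precision = prec, f1 = f1,
                 confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
                 decision_threshold = threshold,
                 precision_undefined = undef),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("sensitivity %.3f  specificity %.3f  accuracy %.3f  precision %.3f  F1 %.3f (threshold %.2f)\n",
              x$sensitivity, x$specificity, x$accuracy, x$precision, x$f1,
              x$decision_threshold))
  invisible(x)
}

# evaluate a named metric on (scores, labels)
.metric_fun <- function(metric, threshold = 0.5) {
  if (is.function(metric)) return(metric)
  switch(metric,
         auroc = function(s, y) auroc(s, y),
         sensitivity = ,
         specificity = ,
         accuracy = ,
         precision = ,
         f1 = function(s, y) threshold_metrics(s, y, threshold)[[metric]],
         stop("unknown metric: ", metric))
}

#' Percentile bootstrap confidence interval for a performance metric
#'
#' Class-stratified resampling: each replicate draws positives from
#' positives and negatives from negatives, with replacement, so every
#' replicate contains both classes. The interval is the 2.5/97.5 percentile
#' of the replicate metric values.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 class labels.
#' @param metric metric name (\code{"auroc"}, \code{"sensitivity"},
#'   \code{"specificity"}, \code{"accuracy"}, \code{"precision"},
#'   \code{"f1"}) or a function \code{(scores, labels) -> value}.
#' @param B number of bootstrap replicates (default 1000, minimum 100).
#' @param seed integer RNG seed.
#' @param threshold decision threshold for the threshold metrics.
#' @return numeric vector \code{c(lower, upper)}.
#' @export
bootstrap_ci <- function(scores, labels, metric = "auroc", B = 1000,
                         seed = 1L, threshold = 0.5) {
  stopifnot(B >= 100)
  labels <- as.integer(labels)
  fn <- .metric_fun(metric, threshold)
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  if (length(pos) == 0L || length(neg) == 0L) stop("both classes must be present")
  set.seed(seed)
  vals <- vapply(seq_len(B), function(b) {
    idx <- c(sample(pos, length(pos), replace = TRUE),
             sample(neg, length(neg), replace = TRUE))
    fn(scores[idx], labels[idx])
  }, numeric(1))
  unname(stats::quantile(vals, c(0.025, 0.975), type = 7))
}

#' Full six-metric report with confidence intervals
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 class labels.
#' @param threshold decision threshold for the threshold metrics.
#' @param B bootstrap replicates for the intervals (0 to skip).
#' @param seed integer RNG seed for the bootstrap.
#' @return data.frame with columns \code{metric}, \code{value},
#'   \code{ci_lower}, \code{ci_upper}.
#' @export
metric_table <- function(scores, labels, threshold = 0.5, B = 1000,
                         seed = 1L) {
  tm <- threshold_metrics(scores, labels, threshold)
  metrics <- c("auroc", "sensitivity", "specificity", "accuracy",
               "precision", "f1")
  vals <- c(auroc(scores, labels), tm$sensitivity, tm$specificity,
            tm$accuracy, tm$precision, tm$f1)
  lo <- hi <- rep(NA_real_, length(metrics))
  if (B >= 100) {
    for (i in seq_along(metrics)) {
      ci <- bootstrap_ci(scores, labels, metrics[i], B = B,
                         seed = seed + i, threshold = threshold)
      lo[i] <- ci[1]; hi[i] <- ci[2]
    }
  }
  data.frame(metric = metrics, value = vals, ci_lower = lo, ci_upper = hi)
}

#' Patient-grouped k-fold cross-validation of the classifier
#'
#' Folds are assigned by patient so no patient's samples span folds; each
#' fold's model is trained on the remaining folds and evaluated on the held
#' fold with the six standard metrics. Reported as per-fold values plus
#' mean and SD per metric.
#'
#' @param samples a \code{labeled_samples} set.
#' @param k number of folds (default 5); requires at least k patients.
#' @param seed integer RNG seed (fold assignment and fits).
#' @param threshold decision threshold for the threshold metrics.
#' @param trainer function \code{(train_samples, seed) -> model} with a
#'   \code{predict} method; defaults to \code{\link{tachynet}} with its
#'   default hyperparameters.
#' @return list with \code{folds} (per-fold metric data.frame) and
#'   \code{summary} (mean and SD per metric).
#' @export
grouped_cv <- function(samples, k = 5, seed = 1L, threshold = 0.5,
                       trainer = NULL) {
  fold_id <- .patient_folds(samples$patient_id, k, seed)
  if (is.null(trainer)) {
    trainer <- function(tr, seed) tachynet(tr, seed = seed)
  }
  rows <- list()
  for (f in seq_len(k)) {
    tr <- subset_samples(samples, which(fold_id != f))
    te <- subset_samples(samples, which(fold_id == f))
    if (length(unique(tr$label)) < 2L || length(unique(te$label)) < 2L) next
    model <- trainer(tr, seed + f)
    s <- predict(model, te)
    tm <- threshold_metrics(s, te$label, threshold)
    rows[[length(rows) + 1L]] <- data.frame(
      fold = f, auroc = auroc(s, te$label), sensitivity = tm$sensitivity,
      specificity = tm$specificity, accuracy = tm$accuracy,
      precision = tm$precision, f1 = tm$f1)
  }
  folds <- do.call(rbind, rows)
  metrics <- c("auroc", "sensitivity", "specificity", "accuracy",
               "precision", "f1")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(folds[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(folds[[m]]), numeric(1)))
  rownames(summary) <- NULL
  list(folds = folds, summary = summary)
}
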