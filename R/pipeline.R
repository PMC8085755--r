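# End-to-end workflows: large-cohort pretraining and small-cohort transfer.
# Each run echoes its full configuration and a hash of it so artifacts are
# attributable to the exact settings that produced them.

.config_hash <- function(x) {
  .registry_hash(paste(utils::capture.output(utils::str(x)), collapse = "\n"))
}

#' Pretrain the classifier on a cohort and evaluate on held-out patients
#'
#' The pretraining workflow: label every record for tachycardia onset, build
#' the balanced labeled sample set (strided negatives from event-free
#' records, forecast-offset replicated positives from event records), split
#' 80/20 by patient, optionally tune hyperparameters by random search with
#' patient-grouped cross-validation on the training side, train the
#' classifier, and report the six metrics (with bootstrap intervals) on the
#' held-out patients.
#'
#' @param records named list of \code{\link{patient_record}} objects.
#' @param sampling a \code{\link{sampling_config}}.
#' @param hidden_size,learning_rate,epochs,batch_size classifier
#'   hyperparameters (overridden by tuning when \code{tune_budget > 0}).
#' @param tune_budget random-search budget; 0 skips tuning.
#' @param threshold decision threshold for the threshold metrics.
#' @param bootstrap_B bootstrap replicates for metric intervals (0 skips).
#' @param seed integer run seed.
#' @return list of class \code{"pretrain_run"}: \code{model},
#'   \code{metrics} (six-metric table), \code{split} sizes, the echoed
#'   \code{config} and its \code{config_hash}.
#' @export
run_pretrain <- function(records, sampling = sampling_config(),
                         hidden_size = 32, learning_rate = 2e-4,
                         epochs = 20, batch_size = 64, tune_budget = 0,
                         threshold = 0.5, bootstrap_B = 1000, seed = 1L) {
  samples <- build_samples(records, sampling)
  if (length(unique(samples$label)) < 2L) {
    stop("stage 'sample': cohort yields a single class")
  }
  split <- balance_and_split(samples, seed = seed)
  if (tune_budget > 0) {
    tuned <- random_search_cv(split$train, budget = tune_budget, seed = seed,
                              hidden_size = hidden_size,
                              batch_size = batch_size)
    learning_rate <- tuned$best$learning_rate
    epochs <- tuned$best$epochs
  }
  model <- tachynet(split$train, hidden_size = hidden_size,
                    learning_rate = learning_rate, epochs = epochs,
                    batch_size = batch_size, seed = seed)
  scores <- predict(model, split$test)
  metrics <- metric_table(scores, split$test$label, threshold = threshold,
                          B = bootstrap_B, seed = seed)
  config <- list(sampling = unclass(sampling), hidden_size = hidden_size,
                 learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, threshold = threshold,
                 bootstrap_B = bootstrap_B, seed = as.integer(seed))
  structure(list(model = model, metrics = metrics,
                 split = list(n_train = length(split$train$label),
                              n_test = length(split$test$label),
                              test_auroc = metrics$value[metrics$metric == "auroc"]),
                 config = config, config_hash = .config_hash(config)),
            class = "pretrain_run")
}

#' @export
print.pretrain_run <- function(x, ...) {
  cat(sprintf("<pretrain_run> train %d / test %d samples (hash %s)\n",
              x$split$n_train, x$split$n_test, x$config_hash))
  print(x$metrics, digits = 3)
  invisible(x)
}

#' Transfer a pretrained model to a new care setting
#'
#' The transfer workflow: build the new setting's labeled samples (by
#' default with the relaxed 4-hour minimum monitoring of a general ward),
#' assess transfer by patient-grouped k-fold cross-validation — each fold
#' finetunes the pretrained weights on the remaining folds — and finetune on
#' all samples for the returned model. Reported as mean (SD) per metric.
#'
#' @param pretrained a fitted \code{\link{tachynet}} model (or a bundle
#'   directory path for \code{\link{load_tachynet}}).
#' @param records named list of the new setting's patient records.
#' @param sampling a \code{\link{sampling_config}}; the default relaxes
#'   minimum monitoring to 240 minutes.
#' @param learning_rate,epochs,batch_size transfer hyperparameters
#'   (defaults 2e-4, 18, 32).
#' @param folds cross-validation folds (default 5).
#' @param threshold decision threshold.
#' @param seed integer run seed.
#' @return list of class \code{"transfer_run"}: finetuned \code{model},
#'   \code{cv} (per-fold and summary tables), echoed \code{config} and
#'   \code{config_hash}.
#' @export
run_transfer <- function(pretrained, records,
                         sampling = sampling_config(min_monitoring = 240),
                         learning_rate = 2e-4, epochs = 18, batch_size = 32,
                         folds = 5, threshold = 0.5, seed = 1L) {
  if (is.character(pretrained)) pretrained <- load_tachynet(pretrained)
  samples <- build_samples(records, sampling)
  if (length(unique(samples$label)) < 2L) {
    stop("stage 'sample': cohort yields a single class")
  }
  set.seed(seed)
  keep_neg <- which(samples$label == 0L)
  n_pos <- sum(samples$label == 1L)
  if (length(keep_neg) > n_pos) keep_neg <- sort(sample(keep_neg, n_pos))
  bal <- subset_samples(samples, sort(c(which(samples$label == 1L), keep_neg)))

  trainer <- function(tr, s) {
    finetune(pretrained, tr, learning_rate = learning_rate, epochs = epochs,
             batch_size = batch_size, seed = s)
  }
  cv <- grouped_cv(bal, k = folds, seed = seed, threshold = threshold,
                   trainer = trainer)
  model <- finetune(pretrained, bal, learning_rate = learning_rate,
                    epochs = epochs, batch_size = batch_size, seed = seed)
  config <- list(sampling = unclass(sampling), learning_rate = learning_rate,
                 epochs = epochs, batch_size = batch_size, folds = folds,
                 threshold = threshold, seed = as.integer(seed))
  structure(list(model = model, cv = cv, n_samples = length(bal$label),
                 config = config, config_hash = .config_hash(config)),
            class = "transfer_run")
}

#' @export
print.transfer_run <- function(x, ...) {
  cat(sprintf("<transfer_run> %d samples, %d-fold grouped CV (hash %s)\n",
              x$n_samples, x$config$folds, x$config_hash))
  print(x$cv$summary, digits = 3)
  invisible(x)
}
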