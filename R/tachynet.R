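# ---- normalization ---------------------------------------------------------

# Training-set z-scoring statistics for the sequence features and the static
# age covariate. Indicator columns are left untouched; so is any feature with
# (numerically) zero variance.
.norm_stats <- function(samples) {
  P <- dim(samples$features)[3]
  flat <- matrix(aperm(samples$features, c(1, 2, 3)), ncol = P)  # (n*T) x P
  mu <- colMeans(flat)
  sd <- apply(flat, 2, stats::sd)
  degenerate <- !is.finite(sd) | sd <= 1e-12
  mu[degenerate] <- 0; sd[degenerate] <- 1
  age <- samples$static[, "age"]
  age_sd <- stats::sd(age)
  if (!is.finite(age_sd) || age_sd <= 1e-12) { age_mu <- 0; age_sd <- 1 }
  else age_mu <- mean(age)
  list(feat_mean = mu, feat_sd = sd, age_mean = age_mu, age_sd = age_sd,
       feature_names = dimnames(samples$features)[[3]],
       static_names = colnames(samples$static))
}

# Assemble the model input: normalized sequence features with the (partly
# normalized) static vector appended at every time step.
.model_input <- function(samples, stats) {
  n <- dim(samples$features)[1]; T <- dim(samples$features)[2]
  P <- dim(samples$features)[3]
  st <- samples$static
  st[, "age"] <- (st[, "age"] - stats$age_mean) / stats$age_sd
  S <- ncol(st)
  x <- array(NA_real_, c(n, T, P + S))
  for (j in seq_len(P)) {
    x[, , j] <- (samples$features[, , j] - stats$feat_mean[j]) / stats$feat_sd[j]
  }
  for (j in seq_len(S)) x[, , P + j] <- matrix(st[, j], n, T)
  x
}

# Polynomial rolling hash of the feature registry names; guards transfer
# between incompatible featurizations.
.registry_hash <- function(feature_names) {
  h <- 0
  for (b in utf8ToInt(paste(feature_names, collapse = ","))) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

# ---- fitting ---------------------------------------------------------------

#' Fit the tachycardia-onset early-warning classifier
#'
#' Trains a bidirectional LSTM over per-window feature sequences fused with
#' static patient attributes. Each labeled sample is a (time steps x
#' features) matrix — by default 21 sub-window steps of 21 statistical
#' features — to which the 11-value encoded static profile is appended at
#' every step. The network runs one LSTM in each time direction (hidden size
#' per direction given by \code{hidden_size}), concatenates the two final
#' hidden states, and maps them through a dense logistic layer to a risk
#' score in [0, 1]. Training minimizes binary cross-entropy with minibatch
#' Adam; feature normalization statistics are computed from the training
#' samples only and stored in the fitted object.
#'
#' A fixed \code{seed} fixes the weight initialization and batch order, so
#' refitting with the same data and seed reproduces the model exactly.
#'
#' @param samples a \code{labeled_samples} training set containing both
#'   classes (see \code{\link{build_samples}}).
#' @param hidden_size LSTM hidden units per direction (default 32).
#' @param learning_rate Adam step size (default 2e-4).
#' @param epochs training epochs (default 20).
#' @param batch_size minibatch size (default 64).
#' @param seed integer RNG seed.
#' @return object of class \code{"tachynet"}: list with the network
#'   \code{params}, normalization \code{stats}, \code{config},
#'   \code{registry_hash}, and per-epoch training \code{loss}.
#' @seealso \code{\link{predict.tachynet}}, \code{\link{finetune}},
#'   \code{\link{random_search_cv}}
#' @export
tachynet <- function(samples, hidden_size = 32, learning_rate = 2e-4,
                     epochs = 20, batch_size = 64, seed = 1L) {
  if (length(unique(samples$label)) < 2L) {
    stop("training data must contain both classes")
  }
  stopifnot(learning_rate > 0, epochs >= 0, batch_size >= 1)
  stats <- .norm_stats(samples)
  x <- .model_input(samples, stats)
  set.seed(seed)
  fit <- .fit_bilstm(x, samples$label, hidden_size, learning_rate,
                     epochs, batch_size)
  structure(list(params = fit$params, stats = stats,
                 config = list(hidden_size = hidden_size,
                               learning_rate = learning_rate,
                               epochs = epochs, batch_size = batch_size,
                               seed = as.integer(seed)),
                 registry_hash = .registry_hash(stats$feature_names),
                 loss = fit$loss, n_train = length(samples$label),
                 call = match.call()),
            class = "tachynet")
}

#' Predict tachycardia-onset risk scores
#'
#' Applies the stored training-set normalization (never statistics of the
#' new data) and the fitted network; a pure function of the weights and the
#' input, invariant to sample order.
#'
#' @param object a fitted \code{\link{tachynet}} model.
#' @param newdata a \code{labeled_samples} object (labels, if present, are
#'   ignored).
#' @param ... unused.
#' @return numeric vector of risk scores in [0, 1].
#' @export
predict.tachynet <- function(object, newdata, ...) {
  fn <- dimnames(newdata$features)[[3]]
  if (!identical(fn, object$stats$feature_names)) {
    stop("feature registry of 'newdata' does not match the fitted model")
  }
  x <- .model_input(newdata, object$stats)
  .score_bilstm(x, object$params)
}

#' @export
print.tachynet <- function(x, ...) {
  cat("Bidirectional LSTM tachycardia-onset classifier\n")
  cat(sprintf("  features/step : %d sequence + %d static\n",
              length(x$stats$feature_names), length(x$stats$static_names)))
  cat(sprintf("  hidden size   : %d per direction\n", x$config$hidden_size))
  cat(sprintf("  trained       : %d samples, lr %g, %d epochs, batch %d, seed %d\n",
              x$n_train, x$config$learning_rate, x$config$epochs,
              x$config$batch_size, x$config$seed))
  if (length(x$loss)) {
    cat(sprintf("  final training loss: %.4f\n", x$loss[length(x$loss)]))
  }
  invisible(x)
}

#' @export
summary.tachynet <- function(object, ...) {
  npar <- length(.flatten_params(object$params))
  cat("Bidirectional LSTM tachycardia-onset classifier\n\n")
  print(object)
  cat(sprintf("  parameters    : %d\n", npar))
  cat(sprintf("  registry hash : %s\n", object$registry_hash))
  invisible(object)
}

#' @export
coef.tachynet <- function(object, ...) {
  object$params[c("fwd", "bwd", "w_out", "b_out")]
}

#' @export
plot.tachynet <- function(x, ...) {
  graphics::plot(seq_along(x$loss), x$loss, type = "b", pch = 16,
                 xlab = "epoch", ylab = "training loss (BCE)",
                 main = "Training loss", ...)
  invisible(x)
}

# ---- transfer finetuning ---------------------------------------------------

#' Transfer-finetune a fitted model on a new cohort
#'
#' @param object a fitted model.
#' @param ... passed to methods.
#' @export
finetune <- function(object, ...) UseMethod("finetune")

#' Continue training a fitted classifier on data from a new care setting
#'
#' Optimization restarts from the pretrained weights with the transfer
#' hyperparameters; normalization statistics are recomputed on the new
#' training samples (the new setting's feature scales differ). The defaults
#' are the standard transfer configuration (learning rate 2e-4, 18 epochs,
#' batch 32). With \code{epochs = 0} the weights are returned unchanged.
#'
#' @param object a fitted \code{\link{tachynet}} model.
#' @param samples \code{labeled_samples} from the new setting.
#' @param learning_rate,epochs,batch_size transfer hyperparameters.
#' @param seed integer RNG seed for batch order.
#' @param ... unused.
#' @return a new \code{"tachynet"} object.
#' @export
finetune.tachynet <- function(object, samples, learning_rate = 2e-4,
                              epochs = 18, batch_size = 32, seed = 1L, ...) {
  fn <- dimnames(samples$features)[[3]]
  if (.registry_hash(fn) != object$registry_hash) {
    stop("feature registry mismatch: cannot finetune across featurizations")
  }
  stats <- .norm_stats(samples)
  out <- object
  out$stats <- stats
  out$config <- list(hidden_size = object$config$hidden_size,
                     learning_rate = learning_rate, epochs = epochs,
                     batch_size = batch_size, seed = as.integer(seed))
  out$n_train <- length(samples$label)
  if (epochs > 0) {
    x <- .model_input(samples, stats)
    set.seed(seed)
    fit <- .fit_bilstm(x, samples$label, object$config$hidden_size,
                       learning_rate, epochs, batch_size,
                       params = object$params)
    out$params <- fit$params
    out$loss <- fit$loss
  } else {
    out$loss <- numeric(0)
  }
  out
}

# ---- hyperparameter search -------------------------------------------------

# fold assignment by patient: every sample of a patient lands in one fold
.patient_folds <- function(patient_id, k, seed) {
  patients <- sort(unique(patient_id))
  if (length(patients) < k) stop("need at least ", k, " patients for ", k, " folds")
  set.seed(seed)
  fold_of <- stats::setNames(sample(rep_len(seq_len(k), length(patients))),
                             patients)
  unname(fold_of[patient_id])
}

#' Random-search hyperparameter tuning with patient-grouped cross-validation
#'
#' Draws \code{budget} (learning rate, epochs) pairs uniformly from the
#' standard grids — learning rate 1e-4 to 1e-2 in steps of 1e-4, epochs 5 to
#' 100 in steps of 10 — and scores each by mean validation binary
#' cross-entropy over patient-grouped k-fold cross-validation, returning the
#' minimizer.
#'
#' @param samples \code{labeled_samples} training set.
#' @param budget number of configurations to try.
#' @param seed integer RNG seed (search draws, folds, and fits).
#' @param folds number of CV folds (default 5).
#' @param hidden_size,batch_size fixed architecture/batch settings.
#' @return list with \code{best} (learning_rate, epochs, val_loss) and the
#'   full \code{trace} data.frame.
#' @export
random_search_cv <- function(samples, budget = 10, seed = 1L, folds = 5,
                             hidden_size = 32, batch_size = 64) {
  stopifnot(budget >= 1)
  fold_id <- .patient_folds(samples$patient_id, folds, seed)
  lr_grid <- seq(1e-4, 1e-2, by = 1e-4)
  ep_grid <- seq(5L, 100L, by = 10L)
  set.seed(seed)
  lrs <- sample(lr_grid, budget, replace = TRUE)
  eps <- sample(ep_grid, budget, replace = TRUE)
  val_loss <- numeric(budget)
  for (i in seq_len(budget)) {
    losses <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- subset_samples(samples, which(fold_id != f))
      va <- subset_samples(samples, which(fold_id == f))
      if (length(unique(tr$label)) < 2L || length(va$label) == 0L) {
        losses[f] <- NA_real_; next
      }
      fit <- tachynet(tr, hidden_size = hidden_size, learning_rate = lrs[i],
                      epochs = eps[i], batch_size = batch_size,
                      seed = seed + 1000L * i + f)
      losses[f] <- .bce(predict(fit, va), va$label)
    }
    val_loss[i] <- mean(losses, na.rm = TRUE)
  }
  trace <- data.frame(learning_rate = lrs, epochs = eps, val_loss = val_loss)
  best <- which.min(val_loss)
  list(best = list(learning_rate = lrs[best], epochs = eps[best],
                   val_loss = val_loss[best]),
       trace = trace)
}

# ---- serialization ---------------------------------------------------------

#' Save a fitted classifier as a plain-text model bundle
#'
#' The bundle is a directory: \code{weights.json} (flattened parameters at
#' full precision), \code{stats.json} (normalization statistics),
#' \code{config.yaml}, and \code{registry.txt} with the feature-name hash.
#'
#' @param model a fitted \code{\link{tachynet}} model.
#' @param dir target directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
save_tachynet <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(theta = .flatten_params(model$params),
                            D = model$params$D, H = model$params$H,
                            loss = model$loss, n_train = model$n_train),
                       file.path(dir, "weights.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(model$stats, file.path(dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(model$config, file.path(dir, "config.yaml"))
  writeLines(c(model$registry_hash, model$stats$feature_names),
             file.path(dir, "registry.txt"))
  invisible(dir)
}

#' Load a model bundle written by \code{\link{save_tachynet}}
#'
#' @param dir bundle directory.
#' @return a \code{"tachynet"} object.
#' @export
load_tachynet <- function(dir) {
  w <- jsonlite::read_json(file.path(dir, "weights.json"), simplifyVector = TRUE)
  stats <- jsonlite::read_json(file.path(dir, "stats.json"), simplifyVector = TRUE)
  config <- yaml::read_yaml(file.path(dir, "config.yaml"))
  reg <- readLines(file.path(dir, "registry.txt"))
  structure(list(params = .unflatten_params(w$theta, w$D, w$H),
                 stats = stats, config = config,
                 registry_hash = reg[1], loss = as.numeric(w$loss),
                 n_train = w$n_train, call = NULL),
            class = "tachynet")
}
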