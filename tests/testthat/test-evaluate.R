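test_that("AUROC follows the rank/pair-counting definition", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(0:1, 5)), 0.5)
  expect_equal(auroc(c(0.9, 0.8, 0.7, 0.3), c(1, 0, 1, 0)), 0.75)
  expect_error(auroc(1:4, rep(1, 4)), "both classes")
})

test_that("AUROC agrees with brute-force pair counting, ties included", {
  set.seed(71)
  for (rep in 1:40) {
    n <- sample(10:80, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(auroc(s, y), oracle_auroc(s, y), tolerance = 1e-12)
  }
})

test_that("AUROC matches an established reference implementation", {
  set.seed(76)
  for (rep in 1:10) {
    y <- c(0, 1, sample(0:1, 48, replace = TRUE))
    s <- round(stats::runif(50), 2)          # include ties
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, direction = "<",
                                          quiet = TRUE)))
    expect_equal(auroc(s, y), ref, tolerance = 1e-12)
  }
})

test_that("complementing the scores complements the AUROC", {
  set.seed(72)
  for (rep in 1:20) {
    y <- sample(0:1, 30, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- stats::rnorm(30)                    # tie-free
    expect_equal(auroc(s, y) + auroc(-s, y), 1, tolerance = 1e-12)
  }
})

test_that("threshold metrics reproduce the confusion table by hand", {
  # TP 3, FN 1, TN 2, FP 2
  scores <- c(0.9, 0.8, 0.7, 0.2, 0.6, 0.9, 0.1, 0.3)
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0)
  m <- threshold_metrics(scores, labels, threshold = 0.5)
  expect_equal(m$confusion, c(tp = 3L, fn = 1L, tn = 2L, fp = 2L))
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$accuracy, 0.625)
  expect_equal(m$precision, 0.6)
  expect_equal(m$f1, 2 * 0.6 * 0.75 / 1.35, tolerance = 1e-12)
})

test_that("threshold metric edge cases behave as specified", {
  perfect <- threshold_metrics(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "accuracy",
                                "precision", "f1")]),
               c(sensitivity = 1, specificity = 1, accuracy = 1,
                 precision = 1, f1 = 1))
  # nothing predicted positive: sensitivity 0, specificity 1, flagged
  none <- threshold_metrics(c(0.1, 0.2, 0.3, 0.4), c(1, 1, 0, 0), 0.9)
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)
  expect_equal(none$precision, 0)
  expect_true(none$precision_undefined)
  # a threshold below every score: sensitivity 1, specificity 0
  all_pos <- threshold_metrics(c(0.5, 0.6, 0.7, 0.8), c(1, 0, 1, 0), 0.1)
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
})

test_that("bootstrap intervals are seeded, stratified and degenerate-safe", {
  set.seed(73)
  s <- c(stats::rnorm(40, 1), stats::rnorm(40))
  y <- rep(1:0, each = 40)
  ci1 <- bootstrap_ci(s, y, "auroc", B = 200, seed = 5)
  ci2 <- bootstrap_ci(s, y, "auroc", B = 200, seed = 5)
  expect_identical(ci1, ci2)
  expect_lt(ci1[1], ci1[2])
  expect_true(ci1[1] >= 0 && ci1[2] <= 1)
  # identical samples per class: zero-width interval
  ci0 <- bootstrap_ci(rep(c(0.8, 0.2), each = 10), rep(1:0, each = 10),
                      "auroc", B = 100, seed = 1)
  expect_equal(unname(ci0[1]), unname(ci0[2]))
  expect_error(bootstrap_ci(s, y, B = 50), "B >= 100")
})

test_that("percentile bootstrap attains near-nominal coverage", {
  # binormal score model: positives N(1,1), negatives N(0,1);
  # the population AUROC is pnorm(1/sqrt(2))
  truth <- stats::pnorm(1 / sqrt(2))
  set.seed(74)
  hits <- 0L
  reps <- 300L
  for (r in seq_len(reps)) {
    s <- c(stats::rnorm(50, 1), stats::rnorm(50))
    y <- rep(1:0, each = 50)
    ci <- bootstrap_ci(s, y, "auroc", B = 120, seed = r)
    if (truth >= ci[1] && truth <= ci[2]) hits <- hits + 1L
  }
  expect_gt(hits / reps, 0.90)
  expect_lt(hits / reps, 0.99)
})

test_that("the six-metric table has the published layout", {
  set.seed(75)
  s <- c(stats::runif(30, 0.5, 1), stats::runif(30, 0, 0.5))
  y <- rep(1:0, each = 30)
  tab <- metric_table(s, y, B = 100, seed = 2)
  expect_equal(tab$metric, c("auroc", "sensitivity", "specificity",
                             "accuracy", "precision", "f1"))
  expect_true(all(tab$value >= 0 & tab$value <= 1))
  expect_true(all(tab$ci_lower <= tab$value + 1e-12))
  expect_true(all(tab$ci_upper >= tab$value - 1e-12))
})

test_that("grouped cross-validation is patient-disjoint and reproducible", {
  s <- toy_samples(60, sep = 2, n_patients = 10, seed = 6)
  trainer <- function(tr, seed) tachynet(tr, hidden_size = 4, epochs = 3,
                                         learning_rate = 2e-3,
                                         batch_size = 16, seed = seed)
  cv <- grouped_cv(s, k = 5, seed = 2, trainer = trainer)
  expect_equal(nrow(cv$folds), 5)
  expect_equal(cv$summary$metric, c("auroc", "sensitivity", "specificity",
                                    "accuracy", "precision", "f1"))
  fold_id <- tachynet:::.patient_folds(s$patient_id, 5, 2)
  # every patient sits in exactly one fold; folds partition the samples
  expect_equal(length(fold_id), length(s$label))
  by_pat <- tapply(fold_id, s$patient_id, function(v) length(unique(v)))
  expect_true(all(by_pat == 1))
  expect_equal(sort(unique(fold_id)), 1:5)
  cv2 <- grouped_cv(s, k = 5, seed = 2, trainer = trainer)
  expect_identical(cv$folds, cv2$folds)
  expect_error(grouped_cv(toy_samples(10, n_patients = 3), k = 5, seed = 1),
               "at least 5")
})
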