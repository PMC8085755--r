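test_that("backpropagated gradients match central finite differences", {
  set.seed(61)
  B <- 3; T <- 4; D <- 5; H <- 3
  X <- array(stats::rnorm(B * T * D), c(B, T, D))
  y <- c(1, 0, 1)
  p <- tachynet:::.init_params(D, H)
  fp <- tachynet:::.net_forward(X, p)
  g <- tachynet:::.flatten_grads(tachynet:::.net_backward(X, y, p, fp))
  th <- tachynet:::.flatten_params(p)
  eps <- 1e-6
  idx <- sample(length(th), 60)            # spot-check across all blocks
  for (i in idx) {
    up <- th; up[i] <- up[i] + eps
    dn <- th; dn[i] <- dn[i] - eps
    lp <- tachynet:::.bce(
      tachynet:::.net_forward(X, tachynet:::.unflatten_params(up, D, H))$p, y)
    lm <- tachynet:::.bce(
      tachynet:::.net_forward(X, tachynet:::.unflatten_params(dn, D, H))$p, y)
    expect_equal(g[i], (lp - lm) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("training is deterministic under a fixed seed", {
  s <- toy_samples(24, sep = 1)
  m1 <- tachynet(s, hidden_size = 6, epochs = 4, learning_rate = 1e-3,
                 batch_size = 8, seed = 7)
  m2 <- tachynet(s, hidden_size = 6, epochs = 4, learning_rate = 1e-3,
                 batch_size = 8, seed = 7)
  expect_identical(tachynet:::.flatten_params(m1$params),
                   tachynet:::.flatten_params(m2$params))
  m3 <- tachynet(s, hidden_size = 6, epochs = 4, learning_rate = 1e-3,
                 batch_size = 8, seed = 8)
  expect_false(identical(tachynet:::.flatten_params(m1$params),
                         tachynet:::.flatten_params(m3$params)))
})

test_that("the network can drive training loss to near zero on a toy set", {
  s <- toy_samples(40, sep = 1.5, seed = 3)
  m <- tachynet(s, hidden_size = 16, epochs = 200, learning_rate = 5e-3,
                batch_size = 40, seed = 1)
  expect_lt(m$loss[length(m$loss)], 0.05)
})

test_that("single-class training input is refused", {
  s <- toy_samples(20)
  s$label <- rep(1L, 20)
  expect_error(tachynet(s), "both classes")
})

test_that("scores are probabilities, deterministic and order-invariant", {
  s <- toy_samples(30, sep = 1)
  m <- tachynet(s, hidden_size = 6, epochs = 5, learning_rate = 1e-3,
                batch_size = 8, seed = 2)
  p <- predict(m, s)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(p, predict(m, s))
  perm <- sample(length(s$label))
  expect_equal(predict(m, tachynet:::subset_samples(s, perm)), p[perm],
               tolerance = 1e-12)
})

test_that("label shuffling destroys held-out discrimination", {
  aurocs <- vapply(1:3, function(sd) {
    s <- toy_samples(200, sep = 1.5, seed = sd, n_patients = 20)
    set.seed(sd)
    s$label <- sample(s$label)               # break the signal
    tr <- tachynet:::subset_samples(s, 1:120)
    te <- tachynet:::subset_samples(s, 121:200)
    m <- tachynet(tr, hidden_size = 6, epochs = 8, learning_rate = 1e-3,
                  batch_size = 16, seed = sd)
    auroc(predict(m, te), te$label)
  }, numeric(1))
  expect_gte(stats::median(aurocs), 0.35)
  expect_lte(stats::median(aurocs), 0.65)
})

test_that("normalization comes from the training data only", {
  s <- toy_samples(30, sep = 1)
  m <- tachynet(s, hidden_size = 4, epochs = 2, seed = 1)
  shifted <- toy_samples(30, sep = 1)
  shifted$features <- shifted$features + 100   # gross covariate shift
  p1 <- predict(m, shifted)
  # the same shifted data scored twice gives identical results: no stats
  # are recomputed at prediction time
  expect_identical(p1, predict(m, shifted))
  expect_identical(m$stats$feat_mean, tachynet:::.norm_stats(s)$feat_mean)
})

test_that("zero-variance features pass through without producing NaN", {
  s <- toy_samples(20, sep = 1)
  s$features[, , 2] <- 5                       # constant feature
  m <- tachynet(s, hidden_size = 4, epochs = 2, seed = 1)
  expect_equal(m$stats$feat_sd[2], 1)
  expect_false(anyNA(predict(m, s)))
})

test_that("finetuning with zero epochs is the identity on the weights", {
  s <- toy_samples(30, sep = 1)
  m <- tachynet(s, hidden_size = 6, epochs = 3, seed = 1)
  ft <- finetune(m, s, epochs = 0)
  expect_identical(tachynet:::.flatten_params(ft$params),
                   tachynet:::.flatten_params(m$params))
})

test_that("the default transfer configuration is lr 2e-4, 18 epochs, batch 32", {
  fm <- formals(tachynet:::finetune.tachynet)
  expect_equal(fm$learning_rate, 2e-4)
  expect_equal(fm$epochs, 18)
  expect_equal(fm$batch_size, 32)
})

test_that("finetuning refuses a mismatched feature registry", {
  s <- toy_samples(20, P = 4)
  m <- tachynet(s, hidden_size = 4, epochs = 1, seed = 1)
  other <- toy_samples(20, P = 4)
  dimnames(other$features)[[3]] <- paste0("g", 1:4)
  expect_error(finetune(m, other), "registry")
  expect_error(predict(m, other), "registry")
})

test_that("finetuning from pretrained weights continues optimization", {
  s <- toy_samples(60, sep = 1, seed = 5)
  m <- tachynet(s, hidden_size = 6, epochs = 5, learning_rate = 1e-3, seed = 1)
  ft <- finetune(m, s, learning_rate = 1e-3, epochs = 5, batch_size = 16,
                 seed = 2)
  expect_false(identical(tachynet:::.flatten_params(ft$params),
                         tachynet:::.flatten_params(m$params)))
  expect_lte(ft$loss[length(ft$loss)], m$loss[length(m$loss)] + 0.05)
})

test_that("random search samples the stated grids and returns the minimizer", {
  s <- toy_samples(40, sep = 2, n_patients = 10)
  rs <- random_search_cv(s, budget = 2, seed = 4, folds = 5,
                         hidden_size = 4, batch_size = 16)
  expect_equal(nrow(rs$trace), 2)
  expect_true(all(rs$trace$learning_rate >= 1e-4 &
                    rs$trace$learning_rate <= 1e-2))
  # grid lattice: multiples of 1e-4 and epochs in 5,15,...,95
  expect_true(all(abs(rs$trace$learning_rate / 1e-4 -
                        round(rs$trace$learning_rate / 1e-4)) < 1e-9))
  expect_true(all(rs$trace$epochs %in% seq(5, 100, by = 10)))
  expect_equal(rs$best$val_loss, min(rs$trace$val_loss))
  rs2 <- random_search_cv(s, budget = 2, seed = 4, folds = 5,
                          hidden_size = 4, batch_size = 16)
  expect_identical(rs$trace, rs2$trace)
  few <- tachynet:::subset_samples(s, which(s$patient_id %in%
                                              unique(s$patient_id)[1:3]))
  expect_error(random_search_cv(few, budget = 1, folds = 5), "at least 5")
})

test_that("model bundles round-trip through plain-text serialization", {
  dir <- withr::local_tempdir()
  s <- toy_samples(30, sep = 1)
  m <- tachynet(s, hidden_size = 6, epochs = 3, seed = 1)
  save_tachynet(m, dir)
  expect_true(all(file.exists(file.path(dir, c("weights.json", "stats.json",
                                               "config.yaml", "registry.txt")))))
  m2 <- load_tachynet(dir)
  expect_equal(predict(m2, s), predict(m, s), tolerance = 1e-8)
  expect_identical(m2$registry_hash, m$registry_hash)
})
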