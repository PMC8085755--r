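test_that("absolute energy is the sum of squares", {
  expect_equal(abs_energy(c(1, 2, 3)), 14)
  expect_equal(abs_energy(rep(0, 10)), 0)
  expect_equal(abs_energy(rep(3, 7)), 7 * 9)
  expect_error(abs_energy(numeric(0)), "empty")
})

test_that("lagged autocorrelation follows the normalized-autocovariance form", {
  expect_equal(autocorrelation(rep(5, 30), 3), 0)   # zero-variance convention
  expect_equal(autocorrelation(rep(c(1, -1), 20), 1), -1)
  expect_error(autocorrelation(1:5, 5), "smaller")
  expect_error(autocorrelation(1:5, 0), "positive")
  # white noise has near-zero expected lag-40 autocorrelation
  set.seed(41)
  vals <- replicate(300, autocorrelation(stats::rnorm(120), 40))
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("c3 is the mean lagged triple product", {
  expect_equal(c3(rep(2, 10), 1), 8)                # constant -> c^3
  expect_equal(c3(1:6, 1), 52.5)
  expect_error(c3(1:6, 3), "too short")
  expect_error(c3(1:10, 0), "positive")
})

test_that("the trend slope is the least-squares line slope", {
  expect_equal(ts_slope(c(1, 2, 3)), 1)
  expect_equal(ts_slope(rep(4, 10)), 0)
  expect_equal(ts_slope(c(0, 2, 4, 6)), 2)
  expect_error(ts_slope(5), "two samples")
})

test_that("the default registry reproduces the canonical 21-feature order", {
  reg <- feature_registry()
  expect_equal(reg$name, c(
    "hr_mean", "hr_std", "hr_sum", "hr_slope", "hr_abs_energy",
    "hr_c2", "hr_c3", "hr_quantiles_01", "hr_quantiles_03", "hr_quantiles_07",
    "resp_mean", "resp_std", "resp_slope", "resp_abs_energy", "resp_c3",
    "spo2_mean", "spo2_std", "spo2_slope", "spo2_c3", "spo2_abs_energy",
    "all_autocorrelation"))
  # ablation subsets: joint feature only with all three channels
  expect_equal(nrow(feature_registry("hr")), 10)
  expect_equal(nrow(feature_registry(c("hr", "rr"))), 15)
  expect_equal(nrow(feature_registry(c("hr", "spo2"))), 15)
})

test_that("feature vectors on constant channels match closed forms", {
  v <- extract_feature_vector(rep(80, 20), rep(16, 20), rep(97, 20),
                              all_autocorr = 0)
  expect_length(v, 21)
  expect_equal(unname(v["hr_mean"]), 80)
  expect_equal(unname(v["hr_std"]), 0)
  expect_equal(unname(v["hr_sum"]), 1600)
  expect_equal(unname(v["hr_slope"]), 0)
  expect_equal(unname(v["hr_abs_energy"]), 128000)
  expect_equal(unname(v[c("hr_quantiles_01", "hr_quantiles_03",
                          "hr_quantiles_07")]), rep(80, 3))
  expect_equal(unname(v["hr_c2"]), 80^3)
  expect_equal(unname(v["spo2_c3"]), 97^3)
  expect_equal(unname(v["resp_std"]), 0)
  expect_error(extract_feature_vector(c(rep(80, 19), NA), rep(16, 20),
                                      rep(97, 20), all_autocorr = 0),
               "incomplete")
})

test_that("every feature agrees with the naive-loop oracle on random windows", {
  set.seed(42)
  for (rep in 1:200) {
    hr <- stats::runif(20, 60, 140)
    rr <- stats::runif(20, 10, 30)
    sp <- stats::runif(20, 90, 100)
    joint <- stats::runif(1, -1, 1)
    got <- extract_feature_vector(hr, rr, sp, all_autocorr = joint)
    expect_equal(unname(got), oracle_feature_vector(hr, rr, sp, joint),
                 tolerance = 1e-9)
  }
  # the lagged-autocorrelation component against its own loop oracle
  for (rep in 1:100) {
    x <- stats::rnorm(120)
    l <- sample(1:60, 1)
    expect_equal(autocorrelation(x, l), oracle_autocorr(x, l),
                 tolerance = 1e-9)
  }
})

test_that("sequence extraction yields the expected geometry", {
  rec <- const_record(300)
  seq1 <- extract_sequence(rec, 120)
  expect_equal(dim(seq1), c(21, 21))
  expect_equal(colnames(seq1), feature_registry()$name)
  # constant record: every time step identical
  expect_true(all(apply(seq1, 2, function(col) all(col == col[1]))))
  expect_error(extract_sequence(const_record(119), 119), "observing window")
  expect_error(extract_sequence(rec, 301), "observing window")
})

test_that("the joint autocorrelation uses the full observing window", {
  set.seed(43)
  hr <- 80 + stats::rnorm(240, 0, 5)
  rr <- 16 + stats::rnorm(240, 0, 2)
  sp <- 96 + stats::rnorm(240, 0, 1)
  rec <- patient_record("x", hr, rr, sp, icu_profile())
  sq <- extract_sequence(rec, 240)
  w <- 121:240
  want <- mean(c(oracle_autocorr(hr[w], 40), oracle_autocorr(rr[w], 40),
                 oracle_autocorr(sp[w], 40)))
  expect_equal(unname(sq[, "all_autocorrelation"]), rep(want, 21),
               tolerance = 1e-9)
})

test_that("windows on a periodic signal shift without hidden state", {
  minute <- 0:299
  rec <- patient_record("p", 70 + (minute %% 5), 14 + (minute %% 5),
                        92 + (minute %% 5), icu_profile())
  a <- extract_sequence(rec, 120)
  b <- extract_sequence(rec, 125)   # shift by one full period
  expect_equal(unclass(a)[, ], unclass(b)[, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})
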