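test_that("PAID scoring maps the 0-80 raw sum onto 0-100 with the distress flag", {
  expect_equal(paid_score(rep(0, 20))$total, 0)
  expect_equal(paid_score(rep(4, 20))$total, 100)
  # raw sum 32 -> 40, the boundary of significant distress (inclusive)
  items <- c(rep(2, 16), rep(0, 4))
  s <- paid_score(items)
  expect_equal(s$total, 40)
  expect_true(s$significant_distress)
  expect_false(paid_score(c(rep(2, 15), 1, rep(0, 4)))$significant_distress)
  expect_error(paid_score(rep(1, 19)), "20 items")
  expect_error(paid_score(c(rep(1, 19), 5)))
})

test_that("QALY AUC uses trapezoidal weights 0.25 and 0.75 years, undiscounted", {
  expect_equal(qaly_auc(0.793, 0.811, 0.793), 0.802)
  expect_equal(qaly_auc(1, 1, 1), 1)
  expect_equal(qaly_auc(0.5, 0.5, 0.5), 0.5)
  # control-arm means reproduce the reported QALY up to input rounding
  expect_equal(qaly_auc(0.766, 0.786, 0.736), 0.764, tolerance = 0.001 / 0.764)
  expect_error(qaly_auc(0.7, NA, 0.7), "missing utility")
})

test_that("mean of per-participant QALYs equals the AUC of mean utilities", {
  set.seed(42)
  for (i in 1:5) {
    u <- matrix(runif(3 * 50, -0.594, 1), ncol = 3)
    expect_equal(mean(qaly_auc(u[, 1], u[, 2], u[, 3])),
                 qaly_auc(mean(u[, 1]), mean(u[, 2]), mean(u[, 3])))
    expect_true(all(qaly_auc(u[, 1], u[, 2], u[, 3]) >= -0.594))
    expect_true(all(qaly_auc(u[, 1], u[, 2], u[, 3]) <= 1))
  }
})

test_that("the 10-14 month validity window is closed and keeps aux values", {
  d <- tibble::tibble(
    id = 1:5,
    month_12 = c(12, 10, 14, 15, NA),
    eq5d_12 = c(0.8, 0.7, 0.6, 0.5, NA),
    paid_12 = c(10, 20, 30, 40, NA)
  )
  out <- apply_validity_window(d)
  expect_equal(out$valid_12m, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$eq5d_12_outcome, c(0.8, 0.7, 0.6, NA, NA))
  # the out-of-window measurement is retained on the original column so it
  # can serve as an imputation predictor
  expect_equal(out$eq5d_12[4], 0.5)
  expect_equal(out$paid_12_outcome[4], NA_real_)
})
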