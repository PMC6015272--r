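m <- default_cost_model()

test_that("ICER vs users matches the trial-scale analysis and declines", {
  sc <- icer_vs_users(m, -152, 0.020, n_grid = c(81, 185, 363, 364, 10000))
  # consistent with the trial-scale ICER of 5550 within rounding of the
  # fixed component (41796/185 = 225.92 vs the reported 226)
  expect_equal(sc$icer[sc$n_users == 185], 5550, tolerance = 10 / 5550)
  expect_equal(round(sc$icer[sc$n_users == 81], -3), 20000)
  expect_true(all(diff(sc$icer) < 0))
  # sign change brackets the break-even count
  expect_gt(sc$icer[sc$n_users == 363], 0)
  expect_lt(sc$icer[sc$n_users == 364], 0)
  flat <- intervention_cost_model(0, 21, 16)
  expect_equal(length(unique(
    icer_vs_users(flat, -152, 0.02, n_grid = c(1, 10, 100))$icer)), 1L)
  expect_error(icer_vs_users(m, -152, 0), "non-zero")
  expect_error(icer_vs_users(m, -152, 0.02, n_grid = 20000), "capacity")
})

test_that("default scaling grid resolves the break-even region", {
  sc <- icer_vs_users(m, -152, 0.020)
  expect_true(all(50:500 %in% sc$n_users))
  expect_true(all(diff(sc$icer) < 0))
  expect_equal(max(sc$n_users), 10000)
})

test_that("break-even user count and its edge cases", {
  be <- breakeven_users(m, -152)
  expect_true(be$exists)
  expect_equal(be$breakeven_n, 363L)
  expect_equal(be$exact_root, 41796 / 115)
  # unrounded components shift the root slightly upward
  beu <- breakeven_users(m, 111 - intervention_cost_per_user(
    m, 185, "unrounded")$cost_per_user, "unrounded")
  expect_equal(beu$breakeven_n, 364L)
  # no healthcare saving: no break-even, signalled not fabricated
  none <- breakeven_users(m, 0)
  expect_false(none$exists)
  expect_true(is.na(none$breakeven_n))
  # zero fixed cost with savings beyond the variable cost: break-even at 1
  be1 <- breakeven_users(intervention_cost_model(0, 21, 16), -152)
  expect_true(be1$exists)
  expect_equal(be1$breakeven_n, 1L)
})

test_that("complete-case analysis equals the primary analysis on complete data", {
  tab <- toy_analysis_table(n = 240, seed = 12, center_sd = 200)
  primary <- analyze_imputed(tab, quiet = TRUE)
  ccafit <- run_cca_analysis(tab, quiet = TRUE)
  expect_equal(tidy(ccafit)$estimate, tidy(primary)$estimate)
  expect_equal(ccafit$retention$fraction, c(1, 1))
})
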