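test_that("permuted-block randomization balances exactly within forced blocks", {
  d <- tibble::tibble(center = rep("C1", 12))
  out <- block_randomize(d, block_sizes = 2, seed = 3)
  expect_equal(as.vector(table(out$arm)), c(6, 6))
  # determinism under the same seed
  out2 <- block_randomize(d, block_sizes = 2, seed = 3)
  expect_identical(out$arm, out2$arm)
  expect_false(identical(out$arm,
                         block_randomize(d, block_sizes = 2, seed = 4)$arm))
  expect_error(block_randomize(tibble::tibble(center = c("C1", NA))),
               "known center")
})

test_that("per-centre imbalance never exceeds half the largest block", {
  d <- tibble::tibble(center = rep(paste0("C", 1:5), times = c(7, 11, 4, 19, 9)))
  worst <- 0
  for (s in 1:300) {
    out <- block_randomize(d, block_sizes = c(2, 4, 6), seed = s)
    imb <- out |>
      dplyr::count(.data$center, .data$arm) |>
      tidyr::pivot_wider(names_from = "arm", values_from = "n",
                         values_fill = 0L) |>
      dplyr::mutate(imb = abs(.data$intervention - .data$control))
    worst <- max(worst, imb$imb)
  }
  expect_lte(worst, 3)
})

test_that("realized arm totals stay near 1:1 and the reference split is attainable", {
  totals <- sapply(1:50, function(s) {
    tr <- generate_trial(trial_config(seed = s))
    table(tr$participants$arm)
  })
  expect_true(all(abs(totals["intervention", ] - 187) <= 21 * 3 / 2))
  expect_true(all(totals["intervention", ] + totals["control", ] == 374))
  # a 185/189-like split (imbalance 4) is within the observed range
  expect_gte(max(abs(totals["intervention", ] - totals["control", ])), 4)
})

test_that("zero-noise configuration collapses to constant arm values", {
  cfg <- tiny_config(seed = 11, n = c(20, 20), centers = 2,
    utility = list(sd = rbind(intervention = c(0, 0, 0),
                              control = c(0, 0, 0))),
    paid = list(sd = rbind(intervention = c(0, 0, 0), control = c(0, 0, 0))),
    cost = list(baseline_cv = 0, innovation_cv = 0),
    center_sd = list(cost = 0, utility = 0, paid = 0))
  tab <- build_analysis_table(generate_trial(cfg))
  for (a in c("intervention", "control")) {
    sub <- tab[tab$arm == a, ]
    for (v in c("eq5d_0", "eq5d_3", "eq5d_12", "paid_0", "paid_12")) {
      expect_equal(length(unique(sub[[v]])), 1L, label = paste(a, v))
    }
    # prescription costs constant up to penny rounding of item splits
    expect_lt(diff(range(sub$cost_presc_pre)), 0.5)
    # the constant utility is a point on the 243-state tariff grid
    expect_true(sub$eq5d_0[1] %in% eq5d_profiles()$utility)
  }
})

test_that("arm-mean calibration error shrinks roughly as 1/sqrt(n)", {
  # centre effects off so the only noise is sampling noise
  err <- sapply(c(100, 1000, 10000), function(n) {
    e <- sapply(1:4, function(s) {
      cfg <- trial_config(n_per_arm = c(n / 2, n / 2), seed = s,
                          center_sd = list(cost = 0, utility = 0, paid = 0))
      tr <- generate_trial(cfg)
      tab <- build_analysis_table(tr)
      int <- tab[tab$arm == "intervention", ]
      # comparable scales: utility absolute, PAID /100, cost relative
      c(abs(mean(int$eq5d_0) - 0.793), abs(mean(int$paid_0) - 18.1) / 100,
        abs(mean(int$cost_baseline) - 1792) / 1792)
    })
    mean(e)
  })
  # two decades of n: errors fall consistent with 1/sqrt(n)
  expect_lt(err[2], err[1])
  expect_lt(err[3], err[2])
  expect_lt(err[3], err[1] / 3)
})

test_that("generated intervention-arm QALYs average to the reference 0.802", {
  q <- sapply(1:25, function(s) {
    tr <- generate_trial(trial_config(seed = s + 300))
    tab <- build_analysis_table(tr)
    int <- tab[tab$arm == "intervention", ]
    ok <- stats::complete.cases(int[, c("eq5d_0", "eq5d_3", "eq5d_12")])
    mean(qaly_auc(int$eq5d_0[ok], int$eq5d_3[ok], int$eq5d_12[ok]))
  })
  expect_equal(mean(q), 0.802, tolerance = 0.006 / 0.802)
})

test_that("missingness rates honour the configuration", {
  cfg <- trial_config(seed = 8)
  tr <- generate_trial(cfg)

  none <- impose_missingness(tr, trial_config(seed = 8, missingness = list(
    q3 = c(0, 0), q12 = c(0, 0), nurse_section = 0, duration = 0)))
  expect_identical(none$participants$eq_mo_12, tr$participants$eq_mo_12)
  expect_identical(none$service_use$count, tr$service_use$count)

  all12 <- impose_missingness(tr, trial_config(seed = 8, missingness = list(
    q3 = c(0, 0), q12 = c(1, 1), nurse_section = 0, duration = 0)))
  expect_true(all(is.na(all12$participants$eq_mo_12)))
  expect_true(all(is.na(all12$participants$month_12)))
  expect_false(anyNA(all12$participants$eq_mo_0))
  expect_false(anyNA(all12$participants$paid_q01_0))

  # default rates: about 70% completion at 12 months in both arms
  comp <- sapply(1:10, function(s) {
    tr_s <- simulate_trial(trial_config(seed = s + 50))
    p <- tr_s$participants
    tapply(!is.na(p$month_12), p$arm, mean)
  })
  expect_equal(mean(comp["intervention", ]), 0.70, tolerance = 0.04 / 0.70)
  expect_equal(mean(comp["control", ]), 0.71, tolerance = 0.04 / 0.71)
  expect_match(simulate_trial(trial_config(seed = 1))$missingness_mechanism,
               "MAR")
  expect_error(impose_missingness(tr, trial_config(seed = 1, missingness =
    list(q3 = c(1.2, 0)))), "\\[0, 1\\]")
})

test_that("writing a trial is deterministic and row counts match", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  simulate_trial(trial_config(seed = 5), path = f1)
  simulate_trial(trial_config(seed = 5), path = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(length(readLines(f1)) - 1L, 374L)
  small <- simulate_trial(tiny_config(seed = 2, n = c(10, 10), centers = 2))
  expect_equal(nrow(small$participants), 20L)
  meta <- jsonlite::read_json(paste0(f1, ".meta.json"))
  expect_equal(meta$n, 374L)
  expect_equal(meta$seeds$global, 5L)
})
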