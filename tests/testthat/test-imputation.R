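test_that("a complete dataset passes through as m identical copies", {
  tab <- toy_analysis_table(n = 60, seed = 2)
  tab$cost_nurse_pre <- tab$cost_baseline
  sp <- imputation_spec(m = 3, seed = 1,
                        variables = c("cost_nurse_pre", "eq5d_0", "paid_0"),
                        aux = character(0))
  out <- mice_pmm(tab, sp)
  expect_s3_class(out, "imputed_data")
  expect_equal(nrow(out), 3 * nrow(tab))
  copies <- split(tibble::as_tibble(out), out$.imp)
  expect_identical(copies[[1]]$eq5d_0, tab$eq5d_0)
  expect_identical(copies[[1]]$cost_nurse_pre, copies[[3]]$cost_nurse_pre)
})

test_that("imputed cells take donor values, observed cells are immutable", {
  set.seed(4)
  tab <- toy_analysis_table(n = 80, seed = 4)
  tab$y <- rnorm(80, 50, 10)
  miss <- sample(80, 20)
  truth <- tab$y
  tab$y[miss] <- NA
  sp <- imputation_spec(m = 4, seed = 9, variables = c("y", "eq5d_0"),
                        aux = character(0))
  out <- mice_pmm(tab, sp)
  for (cp in split(tibble::as_tibble(out), out$.imp)) {
    expect_false(anyNA(cp$y))
    # observed cells identical across copies
    expect_identical(cp$y[-miss], truth[-miss])
    # PMM support: every imputed value is an observed value of the same arm
    for (a in c("control", "intervention")) {
      obs_vals <- truth[-miss][cp$arm[-miss] == a]
      imp_vals <- cp$y[miss][cp$arm[miss] == a]
      expect_true(all(imp_vals %in% obs_vals))
    }
  }
})

test_that("a variable whose donors share one value imputes that value", {
  tab <- toy_analysis_table(n = 40, seed = 6)
  tab$flatvar <- 7
  tab$flatvar[c(3, 17, 25)] <- NA
  out <- mice_pmm(tab, imputation_spec(m = 2, seed = 2,
                                       variables = c("flatvar", "eq5d_0"),
                                       aux = character(0)))
  expect_true(all(out$flatvar == 7))
})

test_that("too few donors is rejected with the variable and arm named", {
  tab <- toy_analysis_table(n = 30, seed = 8)
  tab$sparse <- NA_real_
  tab$sparse[tab$arm == "control"][1:3] <- 1:3  # 3 < k_donors = 5
  tab$sparse[tab$arm == "intervention"][1:8] <- 1:8
  expect_error(
    mice_pmm(tab, imputation_spec(variables = c("sparse", "eq5d_0"),
                                  aux = character(0))),
    "sparse.*control"
  )
})

test_that("imputation under MAR recovers arm means of masked utilities", {
  # mask 25% of 12-month utilities from complete generated data and compare
  # post-imputation arm means with the pre-masking truth
  devs <- sapply(400 + 1:12, function(s) {
    set.seed(s)
    tr <- generate_trial(trial_config(seed = s))
    tab <- build_analysis_table(tr)
    tab <- tab[stats::complete.cases(tab[, c("eq5d_12", "paid_12")]), ]
    truth <- tab$eq5d_12
    n <- nrow(tab)
    mask <- sample(n, round(0.25 * n))
    tab$eq5d_12[mask] <- NA
    out <- mice_pmm(tab, imputation_spec(m = 2, seed = s))
    per_arm <- sapply(split(tibble::as_tibble(out), out$.imp), function(cp) {
      tapply(cp$eq5d_12, cp$arm, mean) - tapply(truth, tab$arm, mean)
    })
    se <- tapply(truth, tab$arm, sd) / sqrt(table(tab$arm))
    rowMeans(per_arm) / as.numeric(se)
  })
  expect_lt(max(abs(rowMeans(devs))), 2)
})

test_that("complete-case filter retains exactly the fully observed rows", {
  tab <- toy_analysis_table(n = 50, seed = 3)
  req <- c("age", "cost_baseline", "eq5d_0", "qaly")
  expect_equal(nrow(cca_filter(tab, req)), 50L)
  tab$qaly[7] <- NA
  tab$cost_baseline[c(7, 20)] <- NA
  out <- cca_filter(tab, req)
  expect_equal(out$id, setdiff(1:50, c(7, 20)))
  ret <- attr(out, "retention")
  expect_equal(sum(ret$retained), 48L)
  expect_equal(ret$n, as.vector(table(tab$arm)))
})
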