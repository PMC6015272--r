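test_that("Rubin pooling matches hand-computed formulas", {
  # estimates {1,2,3}, within-variances {1,1,1}: pooled 2,
  # total = 1 + (1 + 1/3) * var({1,2,3}) = 1 + (4/3) * 1
  p <- pool_rubin(c(1, 2, 3), c(1, 1, 1))
  expect_equal(p$estimate, 2)
  expect_equal(p$se^2, 1 + (4 / 3) * 1)
  expect_equal(p$within, 1)
  # identical estimates: between-variance zero, normal reference
  p0 <- pool_rubin(rep(5, 4), rep(2, 4))
  expect_equal(p0$estimate, 5)
  expect_equal(p0$se^2, 2)
  expect_equal(p0$df, Inf)
  # pooled variance never falls below the mean within-variance
  set.seed(1)
  for (i in 1:10) {
    est <- rnorm(7); v <- runif(7, 0.5, 2)
    expect_gte(pool_rubin(est, v)$se^2, mean(v))
  }
  expect_error(pool_rubin(numeric(0), numeric(0)), "at least one")
})

test_that("ICER arithmetic, quadrants and scale invariance", {
  expect_equal(icer(111, 0.020)$icer, 5550)
  expect_equal(round(icer(111, 1.9)$icer), 58)
  expect_equal(icer(0, 0.3)$icer, 0)
  expect_equal(icer(111, 0.020)$quadrant, "NE")
  expect_equal(icer(-5, 0.020)$quadrant, "SE")
  expect_equal(icer(5, -0.1)$quadrant, "NW")
  z <- icer(100, 0)
  expect_false(z$defined)
  expect_true(is.na(z$icer))
  for (a in c(0.5, 2, 17)) {
    expect_equal(icer(a * 111, a * 0.02)$icer, icer(111, 0.02)$icer)
  }
})

test_that("adjusted mixed model equals OLS when centre variance is zero", {
  tab <- toy_analysis_table(n = 400, seed = 3, center_sd = 0,
                            arm_effect_cost = 150)
  expect_warning(
    fit <- fit_adjusted_difference(tab, "total_cost", "cost_baseline"),
    "singular"
  )
  expect_equal(fit$method, "ols")
  ols <- lm(total_cost ~ arm + age + sex + cvd_history + smoking +
              diabetes_duration + cost_baseline, data = tab)
  expect_equal(fit$estimate, coef(ols)[["armintervention"]], tolerance = 1e-6)
  expect_equal(fit$variance,
               vcov(ols)["armintervention", "armintervention"],
               tolerance = 1e-6)
})

test_that("adjusted model recovers null and non-null arm effects", {
  tab0 <- toy_analysis_table(n = 4000, seed = 7, center_sd = 300)
  fit0 <- fit_adjusted_difference(tab0, "total_cost", "cost_baseline",
                                  quiet = TRUE)
  expect_equal(fit0$method, "lmm")
  expect_lt(abs(fit0$estimate), 3 * fit0$se)
  tabq <- toy_analysis_table(n = 4000, seed = 8, center_sd = 300,
                             arm_effect_qaly = 0.02)
  fitq <- fit_adjusted_difference(tabq, "qaly", "eq5d_0", quiet = TRUE)
  expect_lt(abs(fitq$estimate - 0.02), 3 * fitq$se)
  expect_error(fit_adjusted_difference(tab0[tab0$center == "C1", ],
                                       "qaly", "eq5d_0"), "2 centres")
})

test_that("bootstrap cloud is paired, stratified, and deterministic", {
  tab <- toy_analysis_table(n = 150, seed = 10, center_sd = 0)
  zm <- zero_cost_model()
  cl <- bootstrap_cloud(tab, B = 60, seed = 3, cost_model = zm)
  expect_equal(nrow(cl), 60L)
  cl2 <- bootstrap_cloud(tab, B = 60, seed = 3, cost_model = zm)
  expect_identical(cl, cl2)
  expect_false(identical(
    cl$delta_cost,
    bootstrap_cloud(tab, B = 60, seed = 4, cost_model = zm)$delta_cost))
  expect_error(bootstrap_cloud(tab, B = 0), "at least 1")
  # identical-arm data: the cloud centres on the (null) sample contrast, so
  # its mean sits within a few bootstrap SDs of the origin
  expect_lt(abs(mean(cl$delta_qaly)) / sd(cl$delta_qaly), 3)
  expect_lt(abs(mean(cl$delta_cost)) / sd(cl$delta_cost), 3)
})

test_that("CE-plane quadrants sum to one and respect symmetry", {
  cl <- tibble::tibble(delta_cost = c(10, 20, -5, 3),
                       delta_qaly = c(0.1, 0.2, 0.3, 0.05),
                       delta_paid = 0)
  s <- ce_plane_summary(cl)
  expect_equal(sum(s$proportion), 1)
  expect_equal(s$proportion[s$quadrant == "NE"], 0.75)
  expect_equal(s$proportion[s$quadrant == "SE"], 0.25)
  mirrored <- cl |>
    dplyr::mutate(delta_cost = -delta_cost, delta_qaly = -delta_qaly)
  sm <- ce_plane_summary(mirrored)
  expect_equal(sm$proportion[sm$quadrant == "SW"],
               s$proportion[s$quadrant == "NE"])
  expect_equal(sm$proportion[sm$quadrant == "NW"],
               s$proportion[s$quadrant == "SE"])
  # boundary: zero effect counts as not cost-effective (west side)
  b <- ce_plane_summary(tibble::tibble(delta_cost = 1, delta_qaly = 0,
                                       delta_paid = 0))
  expect_equal(b$proportion[b$quadrant == "NW"], 1)
})

test_that("CEAC limits match the quadrant summary exactly", {
  cl <- normal_cloud(500, mean_cost = 111, mean_qaly = 0.02,
                     sd_cost = 132, sd_qaly = 0.0115, seed = 2)
  cu <- ceac(cl, c(0, 20000, 1e9))
  expect_true(all(cu$probability >= 0 & cu$probability <= 1))
  s <- ce_plane_summary(cl)
  # lambda = 0: cost-saving replicates (south half)
  expect_equal(cu$probability[1],
               sum(s$proportion[s$quadrant %in% c("SE", "SW")]))
  # lambda -> infinity: effect-positive replicates (east half)
  expect_equal(cu$probability[3],
               sum(s$proportion[s$quadrant %in% c("NE", "SE")]))
  expect_error(ceac(cl, c(-5, 10)), ">= 0")
  expect_error(ceac(cl, 1000, effect = "paid"), "PAID")
  expect_error(ceac(cl[0, ], 1000), "empty")
})

test_that("empirical CEAC agrees with the closed normal form", {
  cl <- normal_cloud(20000, 111, 0.02, 132, 0.0115, correlation = 0.2,
                     seed = 5)
  emp <- ceac(cl, c(10000, 20000, 30000))$probability
  thy <- ceac_normal(c(10000, 20000, 30000), 111, 0.02, 132, 0.0115,
                     correlation = 0.2)
  expect_equal(emp, thy, tolerance = 0.02)
})
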