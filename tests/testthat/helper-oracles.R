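# Independent second transcription of the UK TTO value set, written as a
# flat lookup rather than the package's matrix form, so the two paths can
# disagree if either transcription or implementation is wrong.
oracle_eq5d_utility <- function(levels) {
  dec <- list(
    mo = c(`2` = 0.069, `3` = 0.314),
    sc = c(`2` = 0.104, `3` = 0.214),
    ua = c(`2` = 0.036, `3` = 0.094),
    pd = c(`2` = 0.123, `3` = 0.386),
    ad = c(`2` = 0.071, `3` = 0.236)
  )
  if (all(levels == 1)) return(1)
  u <- 1 - 0.081
  for (d in seq_len(5)) {
    if (levels[d] > 1) u <- u - dec[[d]][[as.character(levels[d])]]
  }
  if (any(levels == 3)) u <- u - 0.269
  u
}

# small, fast trial configuration for pipeline tests
tiny_config <- function(seed = 1, n = c(40, 40), centers = 4, ...) {
  trial_config(n_per_arm = n, n_centers = centers, seed = seed, ...)
}

# a complete rectangular analysis-like table with the full section-cost and
# outcome schema, used for model / imputation / bootstrap tests that do not
# need the generator; arm effects are conditional-on-baseline effects on the
# healthcare cost and on the QALY (via the 12-month utility)
toy_analysis_table <- function(n = 200, seed = 1, center_sd = 0,
                               arm_effect_cost = 0, arm_effect_qaly = 0) {
  set.seed(seed)
  centers <- factor(sample(paste0("C", 1:4), n, replace = TRUE))
  arm <- factor(rep(c("control", "intervention"), length.out = n),
                levels = c("control", "intervention"))
  ce <- rnorm(4, 0, center_sd)[as.integer(centers)]
  is_int <- as.numeric(arm == "intervention")
  cost_baseline <- rgamma(n, 1.5, 1 / 1300)
  healthcare <- pmax(0, 1400 + 0.4 * cost_baseline + ce +
                       is_int * arm_effect_cost + rnorm(n, 0, 700))
  eq5d_0 <- pmin(1, rnorm(n, 0.78, 0.2))
  eq5d_3 <- eq5d_0 * 0.7 + rnorm(n, 0.24, 0.06)
  eq5d_12 <- eq5d_0 * 0.7 + rnorm(n, 0.22, 0.08) +
    is_int * arm_effect_qaly / 0.375
  paid_0 <- pmin(100, pmax(0, rnorm(n, 19, 16)))
  tibble::tibble(
    id = seq_len(n), center = centers, arm = arm,
    age = rnorm(n, 65, 9), sex = rbinom(n, 1, 0.7),
    cvd_history = rbinom(n, 1, 0.25), smoking = rbinom(n, 1, 0.15),
    diabetes_duration = rgamma(n, 2, 0.25),
    cost_nurse_pre = cost_baseline, cost_presc_pre = 0, cost_self_pre = 0,
    cost_nurse_m0_3 = 0.25 * healthcare, cost_presc_m0_3 = 0,
    cost_self_m0_3 = 0,
    cost_nurse_m3_12 = 0.75 * healthcare, cost_presc_m3_12 = 0,
    cost_self_m3_12 = 0,
    cost_baseline = cost_baseline, cost_trial = healthcare,
    eq5d_0 = eq5d_0, eq5d_3 = eq5d_3, eq5d_12 = eq5d_12,
    paid_0 = paid_0,
    paid_3 = pmin(100, pmax(0, 2 + 0.7 * paid_0 + rnorm(n, 0, 10))),
    paid_12 = pmin(100, pmax(0, 5 + 0.6 * paid_0 + rnorm(n, 0, 10))),
    total_cost = healthcare,
    qaly = qaly_auc(eq5d_0, eq5d_3, eq5d_12)
  )
}

# a cost model with no intervention cost, so toy arm effects pass through
# derive_endpoints() unshifted
zero_cost_model <- function() {
  intervention_cost_model(0, 0, 0, capacity = 10000, trial_n = 100)
}
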