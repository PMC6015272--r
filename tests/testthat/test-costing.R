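uc <- unit_cost_table()

test_that("service-use sections sum count x unit cost", {
  use <- tibble::tibble(
    id = 1, window = "m0_3", section = "nurse_services",
    service_type = c("gp_surgery", "a_and_e"), count = c(2, 1)
  )
  expect_equal(cost_service_use(use, uc)$cost, 2 * 38 + 167)
  use$count <- c(0, 0)
  expect_equal(cost_service_use(use, uc)$cost, 0)
})

test_that("one missing service makes the whole section missing, order-invariantly", {
  use <- tibble::tibble(
    id = 1, window = "m0_3", section = "nurse_services",
    service_type = c("gp_surgery", "a_and_e", "outpatient"),
    count = c(2, NA, 1)
  )
  expect_true(is.na(cost_service_use(use, uc)$cost))
  set.seed(1)
  for (i in 1:5) {
    perm <- use[sample(nrow(use)), ]
    expect_identical(cost_service_use(perm, uc)$cost,
                     cost_service_use(use, uc)$cost)
  }
  # a different, complete section of the same participant is unaffected
  use2 <- dplyr::bind_rows(use, tibble::tibble(
    id = 1, window = "m0_3", section = "self_report",
    service_type = "podiatrist", count = 3
  ))
  res <- cost_service_use(use2, uc)
  expect_equal(res$cost[res$section == "self_report"], 3 * 44)
})

test_that("bad counts and unknown service types are rejected by name", {
  use <- tibble::tibble(id = 1, window = "m0_3", section = "nurse_services",
                        service_type = "hoverboard_clinic", count = 1)
  expect_error(cost_service_use(use, uc), "hoverboard_clinic")
  use$service_type <- "gp_surgery"; use$count <- -1
  expect_error(cost_service_use(use, uc), "non-negative")
})

test_that("prescriptions are costed monthly over the window months", {
  items <- tibble::tibble(id = 1, timepoint = 3, item = "med_1",
                          monthly_cost = 10)
  status <- tibble::tibble(id = 1, timepoint = 3, presc_status = "recorded")
  out <- cost_prescriptions(items, status)
  expect_equal(out$cost, 30)   # 3-month window
  expect_equal(out$months, 3)

  status12 <- tibble::tibble(id = 1, timepoint = 12, presc_status = "recorded")
  items12 <- tibble::tibble(id = 1, timepoint = 12, item = "a", monthly_cost = 10)
  expect_equal(cost_prescriptions(items12, status12)$cost, 90)  # 9 months

  # explicit no-medication -> zero; blank -> missing
  st <- tibble::tibble(id = 1:2, timepoint = 0,
                       presc_status = c("none", "missing"))
  out <- cost_prescriptions(items[0, ], st)
  expect_equal(out$cost, c(0, NA_real_))
  expect_error(cost_prescriptions(items, tibble::tibble(
    id = 1, timepoint = 6, presc_status = "recorded")), "unknown prescription timepoint")
})

test_that("staff activity costs reproduce the reported schedule", {
  sa <- staff_activity_costs()
  expect_equal(sum(sa$cost), 18783)
  lib <- sa[sa$activity == "librarian_review", ]
  expect_equal(lib$formula_cost, 1 * 52 * 30)
  expect_equal(lib$printed_cost, 1560)
  clin <- sa[sa$activity == "clinical_team_website_interaction", ]
  expect_equal(clin$formula_cost, 605)
  # three rows are known to disagree with any single annualization
  # convention, but none by more than 2%
  expect_equal(sum(sa$rel_diff > 0), 3L)
  expect_false(any(sa$flagged))
  expect_setequal(
    sa$activity[sa$rel_diff > 0],
    c("emails_newsletters_sms", "forum_monitoring_staff",
      "content_update_staff")
  )
  expect_equal(sum(staff_activity_costs(mode = "formula")$cost), 18720)
})

test_that("intervention cost model reproduces the per-participant figures", {
  expect_equal(sum(infrastructure_costs()$annual_cost), 23013)
  m <- default_cost_model()
  expect_equal(m$fixed_annual, 41796)
  pp <- intervention_cost_per_user(m, 185)
  expect_equal(pp$fixed_component, 226)
  expect_equal(pp$training_component, 21)
  expect_equal(pp$facilitation_component, 16)
  expect_equal(pp$cost_per_user, 263)
  # unrounded summation lands just below the rounded-component figure
  ppu <- intervention_cost_per_user(m, 185, "unrounded")
  expect_lt(ppu$cost_per_user, 263)
  expect_gt(ppu$cost_per_user, 262)
  # at server capacity the fixed share nearly vanishes
  expect_equal(intervention_cost_per_user(m, 10000, "unrounded")$cost_per_user,
               41796 / 10000 + 3863 / 185 + 44 / 3 + 0.95)
})

test_that("per-user cost is strictly decreasing in users when fixed > 0", {
  m <- default_cost_model()
  grid <- c(1, 10, 100, 1000, 10000)
  cu <- intervention_cost_per_user(m, grid, "unrounded")$cost_per_user
  expect_true(all(diff(cu) < 0))
  flat <- intervention_cost_model(0, 21, 16)
  expect_equal(length(unique(
    intervention_cost_per_user(flat, grid)$cost_per_user)), 1L)
  expect_error(intervention_cost_per_user(m, 0), "capacity")
  expect_error(intervention_cost_per_user(m, 10001), "capacity")
  expect_error(intervention_cost_model(-1, 2, 3), "non-negative")
})
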