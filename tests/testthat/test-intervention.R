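test_that("a neutral intervention is bit-identical to control under CRN", {
  cfg <- apply_digital_effects(default_config(), theta_r = 1, theta_p = 1,
                               monthly_fee = 0, visit_cost_reduction = 0,
                               specificity = 1)
  a <- simulate_cohort(cfg, "control", n = 2000, seed = 9)
  b <- simulate_cohort(cfg, "digital", n = 2000, seed = 9)
  expect_identical(a$cost, b$cost)
  expect_identical(a$qaly, b$qaly)
  expect_identical(a$classification, b$classification)
  # and the neutrality is independent of the monitor's sensitivity
  cfg2 <- apply_digital_effects(cfg, sensitivity = 0.5)
  b2 <- simulate_cohort(cfg2, "digital", n = 2000, seed = 9)
  expect_identical(a$qaly, b2$qaly)
})

test_that("theta_p = 0 makes relapse on long-term ATD unreachable", {
  cfg <- apply_digital_effects(default_config(), theta_p = 0)
  ex <- cohort_expectation(cfg, "digital")
  expect_equal(ex$class_shares[["relapse_on_long_term_ATD"]], 0,
               tolerance = 1e-12)
  expect_equal(max(ex$occupancy[, "relapse_on_long_term_ATD"]), 0,
               tolerance = 1e-12)
  mc <- simulate_cohort(cfg, "digital", n = 2000, seed = 13)
  expect_equal(sum(mc$classification == "relapse_on_long_term_ATD"), 0L)
})

test_that("monitoring cost arithmetic matches its definition", {
  # digital, fee 30, no reduction, hyperthyroid state (no false positives)
  expect_equal(annual_monitoring_cost("digital", "on_ATD_initial",
                                      monthly_fee = 30), 360 + 92.44)
  # non-hyperthyroid state with perfect specificity
  expect_equal(annual_monitoring_cost("digital", "remission",
                                      monthly_fee = 30, specificity = 1),
               452.44)
  # 30% visit-cost reduction: scheduled component is 92.44 * 0.7
  expect_equal(annual_monitoring_cost("digital", "on_ATD_initial",
                                      monthly_fee = 30,
                                      visit_cost_reduction = 0.30),
               360 + 64.708)
  # expected false-positive component in a non-hyperthyroid state
  expect_equal(annual_monitoring_cost("digital", "long_term_remission",
                                      monthly_fee = 0, specificity = 0.8378),
               92.44 + (1 - 0.8378) * 92.44)
  expect_equal(annual_monitoring_cost("control", "remission"), 92.44)
})

test_that("incremental cost is affine and strictly increasing in the fee", {
  cfg <- default_config(cohort = list(n = 1500L))
  ctl <- simulate_cohort(cfg, "control", seed = 21)
  costs <- vapply(c(0, 30, 60), function(fee) {
    cfgf <- apply_digital_effects(cfg, monthly_fee = fee)
    simulate_cohort(cfgf, "digital", seed = 21)$mean_cost
  }, numeric(1))
  expect_true(all(diff(costs) > 0))
  # under common random numbers trajectories are fee-invariant, so the
  # increments are exactly equal
  expect_equal(costs[3] - costs[2], costs[2] - costs[1], tolerance = 1e-9)
})

test_that("intervention settings are validated", {
  expect_error(apply_digital_effects(default_config(), sensitivity = 1.2))
  expect_error(apply_digital_effects(default_config(), theta_p = 1.5))
  expect_error(apply_digital_effects(default_config(), monthly_fee = -5))
})
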