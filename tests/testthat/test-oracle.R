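test_that("probability mass is conserved and survival never increases", {
  cfg <- default_config()
  for (arm in c("control", "digital")) {
    ex <- cohort_expectation(cfg, arm)
    expect_equal(ex$conservation, rep(1, length(ex$conservation)),
                 tolerance = 1e-12)
    expect_true(all(diff(ex$alive) <= 1e-12))
    expect_true(all(rowSums(ex$occupancy) - 1 < 1e-12))
    expect_true(all(ex$class_shares >= 0))
    expect_equal(sum(ex$class_shares), 1, tolerance = 1e-12)
  }
})

test_that("microsimulation means converge to the oracle (both arms)", {
  cfg <- default_config()
  n <- 10000L
  for (arm in c("control", "digital")) {
    mc <- simulate_cohort(cfg, arm, n = n, seed = 42)
    ex <- cohort_expectation(cfg, arm)
    expect_lt(abs(mc$mean_cost - ex$cost), 3 * mc$se_cost)
    expect_lt(abs(mc$mean_qaly - ex$qaly), 3 * mc$se_qaly)
    for (nm in names(ex$class_shares)) {
      p <- ex$class_shares[[nm]]
      se <- sqrt(max(p * (1 - p), 1e-12) / n)
      expect_lt(abs(mc$class_shares[[nm]] - p), max(3 * se, 1e-9))
    }
  }
})

test_that("expected QALYs are bounded by life years and the horizon", {
  cfg <- default_config()
  ex <- cohort_expectation(cfg, "control")
  expect_lte(ex$qaly, ex$ly)
  expect_lte(ex$ly, cfg$cohort$max_cycles)
})

test_that("costs rise with state costs; discounting shrinks both endpoints", {
  cfg <- default_config()
  base <- cohort_expectation(cfg, "control")
  up <- cohort_expectation(set_param(cfg, "c_hypothyroid", 400), "control")
  expect_gt(up$cost, base$cost)
  up2 <- cohort_expectation(set_param(cfg, "c_long_term_atd", 100), "control")
  expect_gt(up2$cost, base$cost)

  cfg_hi <- set_param(cfg, "discount_rate", 0.08)
  hi <- cohort_expectation(cfg_hi, "control")
  expect_lt(hi$cost, base$cost)
  expect_lt(hi$qaly, base$qaly)
})

test_that("the engine and oracle agree on a config with every pathway active", {
  # exaggerated transition rates exercise relapse churn, re-remission,
  # hypothyroidism and complications heavily
  cfg <- default_config(
    cohort = list(n = 8000L),
    structure = list(subsequent_remission_prob = 0.3)
  )
  cfg <- set_param(cfg, "p_atd_failure", 0.2)
  cfg <- set_param(cfg, "p_relapse", 0.7)
  cfg$intervention$theta_p <- 0.5
  cfg$intervention$theta_r <- 2
  for (arm in c("control", "digital")) {
    mc <- simulate_cohort(cfg, arm, seed = 77)
    ex <- cohort_expectation(cfg, arm)
    expect_lt(abs(mc$mean_cost - ex$cost), 3 * mc$se_cost)
    expect_lt(abs(mc$mean_qaly - ex$qaly), 3 * mc$se_qaly)
    for (nm in names(ex$class_shares)) {
      p <- ex$class_shares[[nm]]
      se <- sqrt(max(p * (1 - p), 1e-12) / cfg$cohort$n)
      expect_lt(abs(mc$class_shares[[nm]] - p), max(3 * se, 1e-9))
    }
  }
})
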