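test_that("a degenerate range produces span zero; ranges are required", {
  cfg <- calibrated_cfg()$config
  tor <- one_way_dsa(cfg, params = c("sens_tft", "monthly_fee"))
  row <- tor[tor$parameter == "sens_tft", ]
  expect_equal(row$span, 0)
  expect_equal(row$icer_low, row$icer_high)
  expect_gt(tor[tor$parameter == "monthly_fee", "span"], 0)
  expect_message(one_way_dsa(default_config()), "skipped")
  expect_error(one_way_dsa(cfg, params = "nope"), "unknown parameter")
})

test_that("collapsing every range to the base value reproduces the base ICER", {
  cfg <- calibrated_cfg()$config
  cfg$parameters$low <- cfg$parameters$base
  cfg$parameters$high <- cfg$parameters$base
  tor <- one_way_dsa(cfg, params = cfg$parameters$name)
  base <- attr(tor, "base_icer")
  expect_true(all(abs(tor$icer_low - base) < 1e-9))
  expect_true(all(abs(tor$icer_high - base) < 1e-9))
  expect_true(all(tor$span < 1e-9))
})

test_that("tornado rows are sorted by span and respond to each endpoint", {
  cfg <- calibrated_cfg()$config
  tor <- suppressMessages(one_way_dsa(cfg))
  expect_true(all(diff(tor$span) <= 0))
  expect_true(all(tor$span >= 0))
  expect_true(all(is.finite(tor$icer_low) & is.finite(tor$icer_high)))
})

test_that("the fee threshold is a true root and shifts affinely", {
  # give the control arm enough extra annual cost that the digital arm is
  # dominant at fee zero, so a positive root exists
  cfg <- calibrated_cfg()$config
  cfg$structure$extra_annual_cost$control <- 200
  fee <- threshold_fee(cfg)
  expect_gt(fee, 0)
  expect_lt(fee, 200)
  # just above the root the digital arm stops being dominant
  above <- set_param(cfg, "monthly_fee", as.numeric(fee) + 0.5)
  above$intervention$monthly_fee <- as.numeric(fee) + 0.5
  ce_above <- compare_arms(cohort_expectation(above, "control"),
                           cohort_expectation(above, "digital"),
                           cfg$economics)
  expect_gt(ce_above$delta_cost, 0)
  below <- set_param(cfg, "monthly_fee", as.numeric(fee) - 0.5)
  below$intervention$monthly_fee <- as.numeric(fee) - 0.5
  ce_below <- compare_arms(cohort_expectation(below, "control"),
                           cohort_expectation(below, "digital"),
                           cfg$economics)
  expect_true(ce_below$digital_dominant)

  # adding an annual control-arm cost of 12*delta moves the root by delta
  cfg2 <- cfg
  cfg2$structure$extra_annual_cost$control <- 200 + 12 * 5
  fee2 <- threshold_fee(cfg2)
  expect_equal(as.numeric(fee2) - as.numeric(fee), 5, tolerance = 0.05)

  # no sign change -> NA with a message
  cfg3 <- cfg
  cfg3$structure$extra_annual_cost$control <- 0
  cfg3$structure$extra_annual_cost$digital <- 5000
  expect_message(out <- threshold_fee(cfg3), "no threshold")
  expect_true(is.na(out))
})

test_that("a degenerate PSA reproduces the base case exactly", {
  cfg <- default_config(cohort = list(n = 500L))
  cfg$parameters$distribution <- "fixed"
  psa <- run_psa(cfg, n_outer = 1L, n_inner = 500L, seed = 6)
  expect_true(all(psa$params[1, ] == cfg$parameters$base))
  # replay the internal seed derivation
  set.seed(6L)
  invisible(sample_parameters(cfg, 1L))
  s <- sample.int(.Machine$integer.max - 1L, 1L)
  ctl <- simulate_cohort(cfg, "control", n = 500, seed = s)
  dig <- simulate_cohort(cfg, "digital", n = 500, seed = s)
  expect_equal(psa$draws$dC, dig$mean_cost - ctl$mean_cost, tolerance = 1e-12)
  expect_equal(psa$draws$dE, dig$mean_qaly - ctl$mean_qaly, tolerance = 1e-12)
})

test_that("PSA is reproducible and its CEAC matches the draw fractions", {
  cfg <- default_config()
  a <- run_psa(cfg, n_outer = 30L, n_inner = 200L, seed = 17)
  b <- run_psa(cfg, n_outer = 30L, n_inner = 200L, seed = 17)
  expect_identical(a$draws, b$draws)
  wtp <- cfg$economics$wtp
  expect_equal(preferred_probability(a, wtp),
               ceac(a, wtp)$prob_cost_effective)
  grid <- c(0, 10000, wtp, 1e6)
  cc <- ceac(a, grid)
  manual <- vapply(grid, function(w) mean(w * a$draws$dE - a$draws$dC > 0),
                   numeric(1))
  expect_equal(cc$prob_cost_effective, manual)
})
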