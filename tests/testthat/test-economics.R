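test_that("discount factors follow (1+r)^(-cycle)", {
  expect_equal(discount_factor(0, 0.045), 1)
  expect_equal(discount_factor(10, 0.045), 0.64393, tolerance = 1e-5)
  expect_equal(discount_factor(0:50, 0), rep(1, 51))
  expect_error(discount_factor(1, -1.5))
})

test_that("ICER, NMB and dominance arithmetic are correct", {
  econ <- list(wtp = 32255)
  ce <- compare_arms(stub_arm(6449.77, 11.159449),
                     stub_arm(6449.77 + 3142.78, 11.159449 + 0.320551),
                     econ, cohort_n = 10000)
  expect_equal(ce$delta_cost, 3142.78, tolerance = 1e-9)
  expect_equal(ce$icer, 9804.30, tolerance = 1e-4)
  expect_false(ce$digital_dominant)

  # NMB formula on chosen per-person values
  ce2 <- compare_arms(stub_arm(9592.55, 11.48), stub_arm(9592.55, 11.48), econ)
  expect_equal(ce2$nmb_control, 11.48 * 32255 - 9592.55, tolerance = 1e-9)
  expect_equal(ce2$nmb_control, 360694.85, tolerance = 1e-2)
  expect_true(ce2$icer_undefined)

  dom <- compare_arms(stub_arm(1000, 10), stub_arm(900, 10.1), econ)
  expect_true(dom$digital_dominant)
  expect_true(is.na(dom$icer))
  wrse <- compare_arms(stub_arm(1000, 10), stub_arm(1100, 9.9), econ)
  expect_true(wrse$digital_dominated)
})

test_that("comparison is antisymmetric and INMB agrees with the ICER test", {
  econ <- list(wtp = 32255)
  set.seed(2)
  for (i in 1:25) {
    c0 <- runif(1, 3000, 12000); c1 <- runif(1, 3000, 12000)
    e0 <- runif(1, 8, 17); e1 <- runif(1, 8, 17)
    ab <- compare_arms(stub_arm(c0, e0), stub_arm(c1, e1), econ)
    ba <- compare_arms(stub_arm(c1, e1), stub_arm(c0, e0), econ)
    expect_equal(ab$delta_cost, -ba$delta_cost, tolerance = 1e-12)
    expect_equal(ab$delta_qaly, -ba$delta_qaly, tolerance = 1e-12)
    expect_equal(ab$inmb, -ba$inmb, tolerance = 1e-9)
    if (ab$delta_cost > 0 && ab$delta_qaly > 0) {
      expect_equal(ab$inmb > 0, ab$icer < econ$wtp)
    }
  }
})

test_that("paired standard errors are used under common random numbers", {
  cfg <- small_cfg()
  ctl <- simulate_cohort(cfg, "control", seed = 3)
  dig <- simulate_cohort(cfg, "digital", seed = 3)
  ce <- compare_arms(ctl, dig, cfg$economics)
  expect_true(ce$paired)
  expect_equal(ce$se_delta_cost,
               sd(dig$cost - ctl$cost) / sqrt(cfg$cohort$n), tolerance = 1e-12)
  # paired SE of the increment is far below the naive pooled SE
  expect_lt(ce$se_delta_qaly, sqrt(ctl$se_qaly^2 + dig$se_qaly^2))
})

test_that("CEAC limit identities and monotonicity hold", {
  set.seed(8)
  draws <- data.frame(dC = rnorm(500, 3000, 2500), dE = rnorm(500, 0.1, 0.2))
  cc <- ceac(draws, c(0, 32255, 1e9))
  expect_equal(cc$prob_cost_effective[1], mean(draws$dC < 0))
  expect_equal(cc$prob_cost_effective[3], mean(draws$dE > 0), tolerance = 1e-3)
  pos <- draws[draws$dE > 0, ]
  cc2 <- ceac(pos, seq(0, 1e5, by = 5000))
  expect_true(all(diff(cc2$prob_cost_effective) >= 0))
  expect_error(ceac(draws, numeric(0)), "non-empty")
})
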