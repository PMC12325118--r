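test_that("multi-year probabilities annualise under a constant hazard", {
  # frozen from high-precision evaluation of 1 - (1-p)^(1/t)
  expect_equal(prob_to_annual(0.05, 1.5), 0.0336175, tolerance = 1e-5)
  expect_equal(prob_to_annual(0.528, 3.73), 0.1823170, tolerance = 1e-5)
  expect_equal(prob_to_annual(0.029, 10.2), 0.0028810, tolerance = 1e-5)
  expect_equal(prob_to_annual(0.30, 1.0), 0.30)
  expect_equal(prob_to_annual(0, 5), 0)
})

test_that("annualisation is monotone in both arguments and rejects bad input", {
  ps <- seq(0.05, 0.9, by = 0.05)
  ts <- c(1, 1.5, 2, 3.73, 5, 10.2)
  for (t in ts) expect_true(all(diff(prob_to_annual(ps, t)) > 0))
  for (p in ps) {
    ann <- vapply(ts, function(t) prob_to_annual(p, t), numeric(1))
    expect_true(all(diff(ann) < 0))
    expect_true(all(ann[ts >= 1] <= p + 1e-12))
  }
  expect_error(prob_to_annual(1, 2), "infinite hazard")
  expect_error(prob_to_annual(0.5, 0), "positive")
})

test_that("beta moment fit reproduces its mean exactly and its target sd", {
  fit <- fit_beta(0.25, 0.20, 0.30)
  expect_equal(fit$shape1, 71.78, tolerance = 1e-4)
  expect_equal(fit$shape2, 215.34, tolerance = 1e-4)
  expect_equal(fit$shape1 / (fit$shape1 + fit$shape2), 0.25, tolerance = 1e-12)
  sd_fit <- sqrt(fit$shape1 * fit$shape2 /
                   ((fit$shape1 + fit$shape2)^2 * (fit$shape1 + fit$shape2 + 1)))
  expect_equal(sd_fit, 0.1 / 3.92, tolerance = 1e-12)
  # symmetric case
  sym <- fit_beta(0.5, 0.45, 0.55)
  expect_equal(sym$shape1, sym$shape2, tolerance = 1e-12)
  expect_error(fit_beta(0.5, -2, 3, name = "p_x"), "p_x")
})

test_that("gamma moment fit matches the acute-care cost row algebra", {
  fit <- fit_gamma(1125.15, 1012.64, 1237.67)
  expect_equal(fit$shape1, 384.16, tolerance = 1e-4)
  expect_equal(fit$shape2, 2.928858, tolerance = 1e-5)
  expect_equal(fit$shape1 * fit$shape2, 1125.15, tolerance = 1e-9)
  # the +/-10% default-range pattern gives the same shape for any mean
  fit2 <- fit_gamma(100, 90, 110)
  expect_equal(fit2$shape1, 384.16, tolerance = 1e-4)
  expect_error(fit_gamma(-1, 0, 1), "positive")
})

test_that("sampled moments recover the fitted mean and sd (Monte Carlo)", {
  n <- 1e5
  set.seed(11)
  for (f in list(fit_beta(0.25, 0.20, 0.30),
                 fit_gamma(1125.15, 1012.64, 1237.67))) {
    x <- sample_fit(f, n)
    target_mean <- if (f$family == "beta") 0.25 else 1125.15
    target_sd <- if (f$family == "beta") 0.1 / 3.92 else 225.03 / 3.92
    expect_lt(abs(mean(x) - target_mean), 3 * sd(x) / sqrt(n))
    expect_lt(abs(sd(x) - target_sd), 3 * target_sd / sqrt(2 * n))
  }
})

test_that("every non-fixed parameter's PSA draws recover base and range sd", {
  cfg <- default_config()
  n <- 2e4
  set.seed(4)
  draws <- sample_parameters(cfg, n)
  tab <- cfg$parameters
  for (i in seq_len(nrow(tab))) {
    x <- draws[, tab$name[i]]
    if (tab$distribution[i] %in% c("fixed", "uniform")) {
      expect_true(all(x == tab$base[i]))
      next
    }
    expect_lt(abs(mean(x) - tab$base[i]), 3 * sd(x) / sqrt(n))
    target_sd <- (tab$high[i] - tab$low[i]) / 3.92
    expect_lt(abs(sd(x) - target_sd), 3 * target_sd / sqrt(2 * n))
  }
})
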