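test_that("the same seed reproduces a cohort bit-for-bit", {
  cfg <- small_cfg()
  a <- simulate_cohort(cfg, "control", seed = 123)
  b <- simulate_cohort(cfg, "control", seed = 123)
  expect_identical(a$cost, b$cost)
  expect_identical(a$qaly, b$qaly)
  expect_identical(a$classification, b$classification)
  c2 <- simulate_cohort(cfg, "control", seed = 124)
  expect_false(identical(a$cost, c2$cost))
})

test_that("certain death ends accrual after the first cycle", {
  cfg <- small_cfg(mortality = list(type = "table", age = 0:110,
                                    qx = rep(1, 111)))
  res <- simulate_cohort(cfg, "control", n = 100, seed = 1)
  expect_true(all(res$ly == 1))
  expect_true(all(res$qaly == param_value(cfg, "u_atd")))
  expect_true(all(!res$alive_at_end))
})

test_that("surviving the relapse window moves patients to long-term remission", {
  # no deaths, failures, relapses or complications: after the 2-year ATD
  # course plus the 5-year window every patient is in long-term remission
  cfg <- small_cfg(mortality = list(type = "table", age = 0:110,
                                    qx = c(rep(0, 110), 1)))
  for (nm in c("p_atd_failure", "p_relapse", "p_hypothyroidism", "p_tao",
               "p_atrial_fibrillation", "p_heart_failure", "p_osteoporosis",
               "p_fracture", "p_thyroid_cancer")) {
    cfg <- set_param(cfg, nm, 0)
  }
  res <- simulate_cohort(cfg, "control", n = 50, seed = 2, trace = TRUE)
  k <- cfg$structure$atd_course_years
  m <- cfg$structure$remission_window_years
  labels <- res$trajectory_labels[res$trajectory]
  dim(labels) <- dim(res$trajectory)
  expect_true(all(labels[, 1:k] == "on_ATD_initial"))
  expect_true(all(labels[, (k + 1):(k + m)] == "remission"))
  expect_true(all(labels[, k + m + 1] == "long_term_remission"))
  expect_true(all(res$classification == "long_term_remission"))
})

test_that("per-patient accrual respects utility and horizon bounds", {
  cfg <- small_cfg()
  res <- simulate_cohort(cfg, "digital", seed = 5)
  expect_true(all(res$qaly <= res$ly + 1e-12))
  expect_true(all(res$ly <= cfg$cohort$max_cycles))
  expect_true(all(res$qaly >= 0))
  expect_true(all(res$cost >= 0))
})

test_that("trajectory classification applies the priority order first-match", {
  fixtures <- list(
    list(states = c("on_ATD_initial", "remission", "long_term_remission"),
         comp = NA),
    list(states = c("on_ATD_initial", "remission",
                    "relapse_on_long_term_ATD", "remission",
                    "long_term_remission"), comp = NA),
    list(states = c("on_ATD_initial", "hypothyroid"), comp = "TAO"),
    list(states = c("on_ATD_initial", "remission",
                    "relapse_on_long_term_ATD", "hypothyroid"), comp = NA),
    list(states = c("on_ATD_initial"), comp = NA),
    list(states = c("on_ATD_initial", "remission", "long_term_remission"),
         comp = "heart_failure")
  )
  cats <- c("complication", "hypothyroid", "long_term_remission",
            "relapse_on_long_term_ATD")
  perms <- list(cats, rev(cats), cats[c(2, 1, 4, 3)], cats[c(3, 4, 1, 2)],
                cats[c(4, 2, 3, 1)])
  for (prio in perms) {
    for (fx in fixtures) {
      has <- c(
        complication = !is.na(fx$comp),
        hypothyroid = "hypothyroid" %in% fx$states,
        long_term_remission = "long_term_remission" %in% fx$states,
        relapse_on_long_term_ATD = "relapse_on_long_term_ATD" %in% fx$states
      )
      hit <- prio[has[prio]]
      want <- if (length(hit)) hit[1] else "other"
      expect_identical(classify_trajectory(fx$states, fx$comp, prio), want)
    }
  }
  # defaults: a complication outranks later long-term remission
  expect_identical(
    classify_trajectory(c("on_ATD_initial", "remission",
                          "long_term_remission"), "TAO"),
    "complication")
  expect_identical(classify_trajectory("on_ATD_initial"), "other")
})

test_that("dying patients keep their classification flags", {
  # moderate mortality; classification shares must match between the engine's
  # compact state representation and a full trajectory replay
  cfg <- small_cfg()
  res <- simulate_cohort(cfg, "control", n = 400, seed = 31, trace = TRUE)
  replay <- vapply(seq_len(400), function(i) {
    visited <- res$trajectory_labels[res$trajectory[i, ]]
    classify_trajectory(visited[!is.na(visited)],
                        as.character(res$complication[i]),
                        cfg$structure$classification_priority)
  }, character(1))
  expect_identical(as.character(res$classification), replay)
})
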