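#' Miniature model configurations with closed-form solutions
#'
#' Builds degenerate configurations whose expected discounted life years,
#' QALYs and costs have closed forms, used to verify the simulation engine
#' and the deterministic oracle against independent arithmetic.
#'
#' * `two_state`: alive/dead. A flat annual death probability `death_prob`
#'   and no disease transitions, utility 1 and a constant annual cost
#'   `annual_cost` in every alive state. Expected discounted life years are a
#'   geometric sum: with `x = (1 - d)/(1 + r)`, `E = (1 - x^T)/(1 - x)`,
#'   which approaches `1/(1 - x)` for a long horizon (e.g. 7.2069 for
#'   `d = 0.1`, `r = 0.045`).
#' * `three_state`: start/hypothyroid/dead. The patient starts in an ATD
#'   state it can never complete, moving to the hypothyroid state with annual
#'   probability `failure_prob` (utility `utility_second`, annual cost
#'   `cost_second`), with the same flat death probability.
#'
#' Toy cohorts enter at age 0 with a flat synthetic life table and run 110
#' cycles, long enough that horizon truncation is below 1e-6 of the
#' infinite-horizon closed form at the default discount rate.
#'
#' @param kind `"two_state"` or `"three_state"`.
#' @param death_prob Flat annual death probability.
#' @param discount_rate Annual discount rate.
#' @param annual_cost Annual cost accrued in every alive state.
#' @param failure_prob (`three_state`) annual probability of leaving the
#'   start state.
#' @param utility_second,cost_second (`three_state`) utility weight and
#'   annual cost of the second alive state.
#' @return A validated `thyrocea_config`.
#' @seealso [toy_closed_form()] for the matching analytic values.
#' @export
#' @examples
#' cfg <- make_toy_config("two_state", death_prob = 0.1, discount_rate = 0.045)
#' cohort_expectation(cfg, "control")$qaly  # ~ 1.045/0.145
make_toy_config <- function(kind = c("two_state", "three_state"),
                            death_prob = 0.1, discount_rate = 0.045,
                            annual_cost = 0, failure_prob = 0.2,
                            utility_second = 0.5, cost_second = 0) {
  kind <- match.arg(kind)
  max_cycles <- 110L
  config <- default_config()
  pars <- config$parameters
  set <- function(tab, name, base, horizon = NA_real_) {
    i <- match(name, tab$name)
    tab$base[i] <- base
    tab$low[i] <- min(tab$low[i], base)
    tab$high[i] <- max(tab$high[i], base)
    tab$horizon_years[i] <- horizon
    tab
  }
  for (nm in c("p_relapse", "p_hypothyroidism", "p_tao",
               "p_atrial_fibrillation", "p_heart_failure", "p_osteoporosis",
               "p_fracture", "p_thyroid_cancer")) {
    pars <- set(pars, nm, 0)
  }
  for (nm in c("c_acute_care", "c_tao", "c_atrial_fibrillation",
               "c_heart_failure", "c_osteoporosis", "c_fracture",
               "c_thyroid_cancer", "c_hypothyroid", "c_long_term_atd",
               "monthly_fee")) {
    pars <- set(pars, nm, 0)
  }
  pars <- set(pars, "u_atd", 1)
  pars <- set(pars, "u_remission", 1)
  pars <- set(pars, "u_hypothyroid", 1)
  pars <- set(pars, "c_tft_visit", annual_cost)
  pars <- set(pars, "discount_rate", discount_rate)

  if (kind == "two_state") {
    pars <- set(pars, "p_atd_failure", 0)
    atd_years <- 2L
  } else {
    pars <- set(pars, "p_atd_failure", failure_prob)
    pars <- set(pars, "u_hypothyroid", utility_second)
    pars <- set(pars, "c_hypothyroid", cost_second)
    atd_years <- max_cycles + 1L  # the ATD course never completes
  }

  config$parameters <- pars
  config$economics$discount_rate <- discount_rate
  config$structure$atd_course_years <- atd_years
  config$structure$subsequent_remission_prob <- 0
  config$cohort <- list(start_age = 0L, n = 10000L, max_cycles = max_cycles,
                        cycle_length_years = 1)
  config$mortality <- list(type = "table",
                           age = 0:110,
                           qx = c(rep(death_prob, 110), 1))
  validate_config(config)
}

#' Closed-form expectations for the toy configurations
#'
#' Independent geometric-series arithmetic for the configurations produced by
#' [make_toy_config()], on the same truncated horizon the engine uses
#' (accrual at cycle start, `T` cycles).
#'
#' @inheritParams make_toy_config
#' @param cycles Horizon in cycles (the toy default is 110).
#' @return A list with `ly` (discounted life years), `qaly` and `cost`.
#' @export
toy_closed_form <- function(kind = c("two_state", "three_state"),
                            death_prob = 0.1, discount_rate = 0.045,
                            annual_cost = 0, failure_prob = 0.2,
                            utility_second = 0.5, cost_second = 0,
                            cycles = 110L) {
  kind <- match.arg(kind)
  gsum <- function(x, T) if (abs(1 - x) < 1e-14) T else (1 - x^T) / (1 - x)
  x <- (1 - death_prob) / (1 + discount_rate)
  ly <- gsum(x, cycles)
  if (kind == "two_state") {
    list(ly = ly, qaly = ly, cost = annual_cost * ly)
  } else {
    # occupancy at cycle start t: start state (1-d)^t (1-f)^t,
    # second state (1-d)^t (1 - (1-f)^t)
    xy <- x * (1 - failure_prob)
    s_start <- gsum(xy, cycles)
    s_second <- ly - s_start
    list(
      ly = ly,
      qaly = s_start + utility_second * s_second,
      cost = annual_cost * ly + cost_second * s_second
    )
  }
}
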