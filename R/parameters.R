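#' Default model parameter table
#'
#' Returns the full set of model input parameters: transition probabilities
#' (with the time horizon each was observed over, where multi-year), test
#' characteristics of the digital monitor and of the confirmatory thyroid
#' function test (TFT), state and complication utility weights, annual and
#' one-time costs in 2022 USD, and the annual discount rate. Each row carries
#' the base value, a low/high range, and the distribution family used for
#' probabilistic sampling (`beta` for probabilities, test characteristics and
#' utilities; `gamma` for costs; `fixed` for degenerate quantities).
#'
#' Ranges are interpreted as 95% intervals when moment-fitting sampling
#' distributions (`sd = (high - low)/3.92`). Parameters whose source gives no
#' range use 90%--110% of the base value. The TFT sensitivity/specificity of
#' 100% are degenerate bounds and are held fixed at 1. The hyperthyroidism
#' prevalence is housed for completeness but unused by the simulated
#' all-incident cohort.
#'
#' @return A data frame with columns `name`, `role`, `base`, `low`, `high`,
#'   `horizon_years` (NA unless the probability was observed over a stated
#'   multi-year window) and `distribution`.
#' @export
#' @examples
#' head(default_parameters())
default_parameters <- function() {
  p <- function(name, role, base, low, high, horizon = NA_real_, dist = "beta") {
    data.frame(name = name, role = role, base = base, low = low, high = high,
               horizon_years = horizon, distribution = dist,
               stringsAsFactors = FALSE)
  }
  rbind(
    p("prevalence_hyperthyroidism", "transition_probability", 0.0720, 0.0576, 0.0864),
    p("p_atd_failure",       "transition_probability", 0.050,  0.040,  0.060,  horizon = 1.5),
    p("p_hypothyroidism",    "transition_probability", 0.029,  0.0232, 0.0348, horizon = 10.2),
    p("p_relapse",           "transition_probability", 0.528,  0.4224, 0.6336, horizon = 3.73),
    p("p_tao",               "transition_probability", 0.250,  0.200,  0.300),
    p("p_atrial_fibrillation", "transition_probability", 0.043, 0.030, 0.050),
    p("p_heart_failure",     "transition_probability", 0.016,  0.011,  0.021),
    p("p_osteoporosis",      "transition_probability", 0.0159, 0.0109, 0.0209),
    p("p_fracture",          "transition_probability", 0.033,  0.028,  0.038),
    p("p_thyroid_cancer",    "transition_probability", 0.0123, 0.009,  0.020),
    p("sens_digital",        "test_characteristic", 0.8713, 0.784,  0.958),
    p("spec_digital",        "test_characteristic", 0.8378, 0.754,  0.9215),
    p("sens_tft",            "test_characteristic", 1.0, 1.0, 1.0, dist = "fixed"),
    p("spec_tft",            "test_characteristic", 1.0, 1.0, 1.0, dist = "fixed"),
    p("u_thyroid_cancer",    "utility", 0.897,  0.852,  0.941),
    p("u_hypothyroid",       "utility", 0.9479, 0.902,  0.997),
    p("u_tao",               "utility", 0.840,  0.798,  0.882),
    p("u_atd",               "utility", 0.860,  0.817,  0.903),
    p("u_osteoporosis",      "utility", 0.910,  0.8645, 0.9555),
    p("u_fracture",          "utility", 0.830,  0.7885, 0.8715),
    p("u_atrial_fibrillation", "utility", 0.810, 0.729, 0.891),
    p("u_heart_failure",     "utility", 0.780,  0.702,  0.858),
    p("u_remission",         "utility", 1.000,  1.000,  1.000, dist = "fixed"),
    p("c_acute_care",        "one_time_cost", 1125.15, 1012.64, 1237.67, dist = "gamma"),
    p("c_tao",               "annual_cost", 386.77, 367.44, 406.11, dist = "gamma"),
    p("c_atrial_fibrillation", "annual_cost", 150.54, 143.02, 158.07, dist = "gamma"),
    p("c_heart_failure",     "annual_cost", 439.63, 417.65, 461.61, dist = "gamma"),
    p("c_osteoporosis",      "annual_cost", 208.49, 198.07, 218.91, dist = "gamma"),
    p("c_fracture",          "annual_cost", 347.41, 330.04, 364.78, dist = "gamma"),
    p("c_thyroid_cancer",    "annual_cost", 149.23, 141.77, 156.69, dist = "gamma"),
    p("c_hypothyroid",       "annual_cost", 250.37, 225.34, 275.41, dist = "gamma"),
    p("c_long_term_atd",     "annual_cost", 48.87, 43.98, 53.76, dist = "gamma"),
    p("monthly_fee",         "annual_cost", 30, 10, 50, dist = "gamma"),
    p("c_tft_visit",         "annual_cost", 92.44, 64.71, 120.17, dist = "gamma"),
    p("discount_rate",       "rate", 0.045, 0.030, 0.050, dist = "fixed")
  )
}

.PARAM_ROLES <- c("transition_probability", "test_characteristic", "utility",
                  "annual_cost", "one_time_cost", "rate")
.PARAM_DISTS <- c("beta", "gamma", "uniform", "fixed")

#' Look up a parameter's base value
#'
#' @param config A model configuration, see [default_config()].
#' @param name Parameter name.
#' @return The base value (numeric scalar).
#' @export
param_value <- function(config, name) {
  i <- match(name, config$parameters$name)
  if (is.na(i)) stop("unknown parameter: ", name, call. = FALSE)
  config$parameters$base[i]
}

#' Convert a multi-year probability to an annual probability
#'
#' Converts a probability observed over `t` years to the per-year probability
#' under a constant-hazard assumption: `1 - (1 - p)^(1/t)`. Used to align
#' literature probabilities (e.g. treatment failure over 1.5 years, relapse
#' over 3.73 years) with the model's one-year cycle.
#'
#' @param p Probability observed over the horizon, in `[0, 1)`.
#' @param t Horizon in years, positive.
#' @return Annual probability.
#' @export
#' @examples
#' prob_to_annual(0.05, 1.5)
#' prob_to_annual(0.528, 3.73)
prob_to_annual <- function(p, t) {
  stopifnot(is.numeric(p), is.numeric(t))
  if (any(t <= 0)) stop("horizon t must be positive", call. = FALSE)
  if (any(p < 0) || any(p >= 1)) {
    stop("p must be in [0, 1); p = 1 implies infinite hazard", call. = FALSE)
  }
  1 - (1 - p)^(1 / t)
}

#' Moment-fit a beta distribution to a mean and a range
#'
#' Treats `[low, high]` as a 95% interval, so `sd = (high - low)/3.92`, and
#' solves the method-of-moments equations. The fitted distribution reproduces
#' the target mean exactly.
#'
#' @param mean Target mean, in (0, 1).
#' @param low,high Range bounds, `low < high`.
#' @param name Optional parameter name used in error messages.
#' @return A list of class `thyrocea_distfit` with elements `family`
#'   (`"beta"`), `shape1` (alpha) and `shape2` (beta).
#' @export
#' @examples
#' fit_beta(0.25, 0.20, 0.30)
fit_beta <- function(mean, low, high, name = NULL) {
  lbl <- if (is.null(name)) "" else paste0(" for '", name, "'")
  if (!(mean > 0 && mean < 1)) stop("beta mean must be in (0,1)", lbl, call. = FALSE)
  if (!(low < high)) stop("need low < high", lbl, call. = FALSE)
  s <- (high - low) / 3.92
  v <- s^2
  if (v >= mean * (1 - mean)) {
    stop("variance too large for a beta distribution", lbl, call. = FALSE)
  }
  nu <- mean * (1 - mean) / v - 1
  structure(list(family = "beta", shape1 = mean * nu, shape2 = (1 - mean) * nu),
            class = "thyrocea_distfit")
}

#' Moment-fit a gamma distribution to a mean and a range
#'
#' Same range-as-95%-interval convention as [fit_beta()]: `sd = (high -
#' low)/3.92`, `shape = (mean/sd)^2`, `scale = sd^2/mean`. The fitted mean
#' equals the target mean exactly.
#'
#' @inheritParams fit_beta
#' @param mean Target mean, positive.
#' @return A list of class `thyrocea_distfit` with elements `family`
#'   (`"gamma"`), `shape1` (shape k) and `shape2` (scale theta).
#' @export
#' @examples
#' fit_gamma(1125.15, 1012.64, 1237.67)
fit_gamma <- function(mean, low, high, name = NULL) {
  lbl <- if (is.null(name)) "" else paste0(" for '", name, "'")
  if (!(mean > 0)) stop("gamma mean must be positive", lbl, call. = FALSE)
  if (!(low < high)) stop("need low < high", lbl, call. = FALSE)
  s <- (high - low) / 3.92
  structure(list(family = "gamma", shape1 = (mean / s)^2, shape2 = s^2 / mean),
            class = "thyrocea_distfit")
}

#' @export
print.thyrocea_distfit <- function(x, ...) {
  cat(sprintf("%s(shape1 = %.6g, shape2 = %.6g)\n", x$family, x$shape1, x$shape2))
  invisible(x)
}

#' Draw random samples from a moment-fitted distribution
#'
#' @param fit A `thyrocea_distfit` from [fit_beta()] or [fit_gamma()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_fit <- function(fit, n) {
  switch(fit$family,
    beta  = rbeta(n, fit$shape1, fit$shape2),
    gamma = rgamma(n, shape = fit$shape1, scale = fit$shape2),
    stop("unsupported family: ", fit$family, call. = FALSE)
  )
}

#' Sample the full parameter set for probabilistic sensitivity analysis
#'
#' Draws every non-fixed parameter from its moment-fitted distribution (beta
#' for probabilities, test characteristics and utilities; gamma for costs).
#' Fixed parameters keep their base value in every draw. Caller is responsible
#' for seeding the RNG.
#'
#' @param config A model configuration.
#' @param n Number of parameter-set draws.
#' @return A numeric matrix with `n` rows and one column per parameter.
#' @export
sample_parameters <- function(config, n) {
  pars <- config$parameters
  out <- matrix(rep(pars$base, each = n), nrow = n,
                dimnames = list(NULL, pars$name))
  for (i in seq_len(nrow(pars))) {
    if (pars$distribution[i] %in% c("fixed", "uniform")) next
    fit <- if (pars$distribution[i] == "gamma") {
      fit_gamma(pars$base[i], pars$low[i], pars$high[i], name = pars$name[i])
    } else {
      fit_beta(pars$base[i], pars$low[i], pars$high[i], name = pars$name[i])
    }
    out[, pars$name[i]] <- sample_fit(fit, n)
  }
  out
}
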