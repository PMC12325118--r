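#' Override a parameter's base value
#'
#' Returns the configuration with the named parameter set to `value` (and
#' its range widened if needed so the table stays valid). Setting
#' `discount_rate` also updates `economics$discount_rate`, which is what the
#' engine discounts with.
#'
#' @param config A model configuration.
#' @param name Parameter name.
#' @param value New base value.
#' @return The modified `thyrocea_config` (not re-validated; sensitivity
#'   analyses probe range endpoints).
#' @export
set_param <- function(config, name, value) {
  i <- match(name, config$parameters$name)
  if (is.na(i)) stop("unknown parameter: ", name, call. = FALSE)
  config$parameters$base[i] <- value
  config$parameters$low[i] <- min(config$parameters$low[i], value)
  config$parameters$high[i] <- max(config$parameters$high[i], value)
  if (name == "discount_rate") config$economics$discount_rate <- value
  config
}

oracle_ce <- function(config) {
  compare_arms(cohort_expectation(config, "control"),
               cohort_expectation(config, "digital"),
               config$economics, cohort_n = config$cohort$n)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-evaluates the incremental cost-effectiveness ratio with each parameter
#' set to its low and high range endpoint in turn, all other inputs at base
#' case. ICERs come from the deterministic cohort-expectation oracle, so the
#' ranking is free of Monte-Carlo noise. Rows are sorted by span
#' (`|icer_high - icer_low|`) descending. Parameters without a range
#' (`low == high`) are skipped with a message unless explicitly requested.
#'
#' @param config A (calibrated) model configuration.
#' @param params Parameter names to vary; default: every parameter with a
#'   non-degenerate range.
#' @return A data frame of class `thyrocea_tornado` with columns `parameter`,
#'   `low`, `high`, `icer_low`, `icer_high`, `span`, plus attribute
#'   `base_icer`.
#' @export
one_way_dsa <- function(config, params = NULL) {
  tab <- config$parameters
  if (is.null(params)) {
    skip <- tab$name[tab$low == tab$high]
    if (length(skip)) {
      message("skipped (no range): ", paste(skip, collapse = ", "))
    }
    params <- tab$name[tab$low < tab$high]
  }
  base_icer <- oracle_ce(config)$icer
  rows <- lapply(params, function(nm) {
    i <- match(nm, tab$name)
    if (is.na(i)) stop("unknown parameter: ", nm, call. = FALSE)
    icer_lo <- oracle_ce(set_param(config, nm, tab$low[i]))$icer
    icer_hi <- oracle_ce(set_param(config, nm, tab$high[i]))$icer
    data.frame(parameter = nm, low = tab$low[i], high = tab$high[i],
               icer_low = icer_lo, icer_high = icer_hi,
               span = abs(icer_hi - icer_lo), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  class(out) <- c("thyrocea_tornado", "data.frame")
  out
}

#' Subscription-fee threshold for digital-arm dominance
#'
#' Finds the monthly subscription fee at which the incremental discounted
#' lifetime cost of the digital arm crosses zero; below it the digital arm
#' is dominant (cheaper and more effective). The incremental cost is affine
#' and strictly increasing in the fee, so the root is unique; it is located
#' by bisection on the deterministic cohort-expectation oracle.
#'
#' @param config A (calibrated) model configuration.
#' @param lower,upper Search interval, USD per month.
#' @param tol Absolute tolerance on the fee, USD per month.
#' @return The threshold fee (numeric), with attributes `delta_cost_at_zero`
#'   and `delta_qaly`; `NA` with a message if the incremental cost does not
#'   change sign on the interval.
#' @export
threshold_fee <- function(config, lower = 0, upper = 200, tol = 0.01) {
  dC_at <- function(fee) {
    cfg <- set_param(config, "monthly_fee", fee)
    cfg$intervention$monthly_fee <- fee
    ce <- oracle_ce(cfg)
    c(ce$delta_cost, ce$delta_qaly)
  }
  lo <- dC_at(lower)
  hi <- dC_at(upper)
  if (sign(lo[1]) == sign(hi[1])) {
    message(sprintf("no threshold in [%.0f, %.0f]: delta cost %.2f at %.0f, %.2f at %.0f",
                    lower, upper, lo[1], lower, hi[1], upper))
    return(structure(NA_real_, delta_cost_at_zero = lo[1], delta_qaly = lo[2]))
  }
  a <- lower; b <- upper
  while (b - a > tol) {
    mid <- (a + b) / 2
    if (sign(dC_at(mid)[1]) == sign(lo[1])) a <- mid else b <- mid
  }
  root <- (a + b) / 2
  structure(root, delta_cost_at_zero = lo[1], delta_qaly = dC_at(root)[2])
}

#' Probabilistic sensitivity analysis
#'
#' Outer loop: every non-fixed parameter is drawn from its moment-fitted
#' distribution (beta for probabilities, test characteristics and utilities;
#' gamma for costs). Inner loop: both arms are microsimulated with
#' `n_inner` patients under common random numbers, and the incremental
#' discounted cost and QALYs are recorded. Fully reproducible from `seed`.
#'
#' @param config A (calibrated) model configuration.
#' @param n_outer Number of parameter-set draws.
#' @param n_inner Patients per arm per draw.
#' @param seed Integer seed for parameter sampling and the per-draw
#'   simulation streams.
#' @return A list of class `thyrocea_psa`: `draws` (data frame `draw`, `dC`,
#'   `dE`), the sampled parameter matrix `params`, and the run settings.
#' @seealso [ceac()], [preferred_probability()]
#' @export
run_psa <- function(config, n_outer = 1000L, n_inner = 1000L, seed = 1L) {
  stopifnot(n_outer >= 1, n_inner >= 1)
  set.seed(as.integer(seed))
  par_draws <- sample_parameters(config, n_outer)
  inner_seeds <- sample.int(.Machine$integer.max - 1L, n_outer)
  i_disc <- match("discount_rate", config$parameters$name)
  disc_sampled <- !is.na(i_disc) &&
    !config$parameters$distribution[i_disc] %in% c("fixed", "uniform")
  dC <- dE <- numeric(n_outer)
  for (i in seq_len(n_outer)) {
    cfg <- config
    cfg$parameters$base <- unname(par_draws[i, ])
    if (disc_sampled) cfg$economics$discount_rate <- par_draws[i, "discount_rate"]
    ctl <- simulate_cohort(cfg, "control", n = n_inner, seed = inner_seeds[i])
    dig <- simulate_cohort(cfg, "digital", n = n_inner, seed = inner_seeds[i])
    dC[i] <- dig$mean_cost - ctl$mean_cost
    dE[i] <- dig$mean_qaly - ctl$mean_qaly
  }
  structure(list(
    draws = data.frame(draw = seq_len(n_outer), dC = dC, dE = dE),
    params = par_draws,
    n_outer = n_outer, n_inner = n_inner, seed = as.integer(seed)
  ), class = "thyrocea_psa")
}

#' Probability that the digital arm is the preferred strategy
#'
#' Fraction of PSA draws with positive incremental net monetary benefit at
#' the willingness-to-pay threshold.
#'
#' @param psa A `thyrocea_psa`.
#' @param wtp Willingness to pay per QALY.
#' @return Numeric in `[0, 1]`.
#' @export
preferred_probability <- function(psa, wtp) {
  mean(wtp * psa$draws$dE - psa$draws$dC > 0)
}

#' @export
print.thyrocea_psa <- function(x, ...) {
  cat(sprintf("<thyrocea_psa> %d draws x %d patients, seed %d\n",
              x$n_outer, x$n_inner, x$seed))
  cat(sprintf("  mean delta cost %.2f, mean delta QALY %.4f\n",
              mean(x$draws$dC), mean(x$draws$dE)))
  invisible(x)
}
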