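#' Apply the digital-monitoring intervention to a configuration
#'
#' Produces the digital-arm configuration. The digital monitor acts through
#' two interpretable, calibratable multipliers:
#'
#' * `theta_p` scales the annual probability that a relapse leads to
#'   long-term antithyroid-drug (ATD) therapy. The mechanism is detection:
#'   a would-be relapse is caught by the monitor with probability equal to
#'   its sensitivity, and a caught relapse is successfully re-treated within
#'   the cycle -- the patient re-enters the remission pathway (relapse-window
#'   clock reset) instead of moving to long-term ATD. The aversion
#'   probability is `(1 - theta_p) * sensitivity / sensitivity_reference`, so
#'   at the reference sensitivity the effective relapse-to-long-term-ATD
#'   probability is exactly `p_relapse * theta_p`, and varying the device
#'   sensitivity (as the tornado analysis does) scales the benefit
#'   proportionally. `theta_p = 1` is the null intervention: bit-identical to
#'   control under common random numbers, whatever the sensitivity.
#' * `theta_r` multiplies the annual probability that a patient on long-term
#'   ATD returns to remission (`subsequent_remission_prob`).
#'
#' All other clinical parameters are unchanged; monitoring economics are
#' handled by [annual_monitoring_cost()]. Multipliers that would push a
#' probability outside `[0, 1]` are clamped with a warning when the engine
#' runs.
#'
#' @param config A model configuration.
#' @param sensitivity,specificity Digital monitor test characteristics
#'   (probabilities).
#' @param monthly_fee Subscription fee, USD per month.
#' @param visit_cost_reduction Fraction in `[0, 1]` by which the scheduled
#'   annual TFT-visit cost is reduced in the digital arm (scenario analysis).
#' @param theta_r Multiplier (`>= 1`) on the subsequent-remission
#'   probability.
#' @param theta_p Multiplier in `(0, 1]` on the effective relapse
#'   probability.
#' @return The digital-arm `thyrocea_config`; run it with
#'   `simulate_cohort(cfg, "digital")`.
#' @export
#' @examples
#' cfg <- apply_digital_effects(default_config(), theta_p = 0.6, theta_r = 2)
#' cfg$intervention$theta_p
apply_digital_effects <- function(config,
                                  sensitivity = config$intervention$sensitivity,
                                  specificity = config$intervention$specificity,
                                  monthly_fee = config$intervention$monthly_fee,
                                  visit_cost_reduction = config$intervention$visit_cost_reduction,
                                  theta_r = config$intervention$theta_r,
                                  theta_p = config$intervention$theta_p) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            monthly_fee >= 0, theta_r >= 0, theta_p >= 0, theta_p <= 1)
  config$intervention$sensitivity <- sensitivity
  config$intervention$specificity <- specificity
  config$intervention$monthly_fee <- monthly_fee
  config$intervention$visit_cost_reduction <- visit_cost_reduction
  config$intervention$theta_r <- theta_r
  config$intervention$theta_p <- theta_p
  # the parameter table is canonical for the engine and for DSA/PSA
  i <- match(c("sens_digital", "spec_digital", "monthly_fee"),
             config$parameters$name)
  config$parameters$base[i] <- c(sensitivity, specificity, monthly_fee)
  config$parameters$low[i] <- pmin(config$parameters$low[i],
                                   config$parameters$base[i])
  config$parameters$high[i] <- pmax(config$parameters$high[i],
                                    config$parameters$base[i])
  validate_config(config)
}

#' Annual monitoring cost for one patient-cycle
#'
#' Control arm: one full-fee thyroid function test (TFT) visit per alive
#' year. Digital arm: twelve months of subscription, one scheduled TFT visit
#' at `(1 - visit_cost_reduction)` of the fee, plus -- in states without
#' active hyperthyroidism, where an alert cannot be a true positive -- a
#' false-positive confirmatory visit with probability `1 - specificity` at
#' the full fee.
#'
#' @param arm `"control"` or `"digital"`.
#' @param state A health-state label (one of the model states).
#' @param monthly_fee,specificity,visit_cost_reduction Intervention settings.
#' @param tft_fee TFT visit fee (USD).
#' @param rng If `TRUE`, sample the false-positive visit; otherwise return
#'   the expected cost.
#' @return Cost for the cycle (USD).
#' @export
#' @examples
#' annual_monitoring_cost("digital", "remission", monthly_fee = 30)
#' annual_monitoring_cost("control", "remission")
annual_monitoring_cost <- function(arm = c("control", "digital"),
                                   state = "remission",
                                   monthly_fee = 30, specificity = 0.8378,
                                   visit_cost_reduction = 0,
                                   tft_fee = 92.44, rng = FALSE) {
  arm <- match.arg(arm)
  if (arm == "control") return(tft_fee)
  nonhyper <- state %in% c("remission", "long_term_remission", "hypothyroid")
  fp <- if (nonhyper) (1 - specificity) else 0
  fp_part <- if (rng) tft_fee * (runif(1) < fp) else tft_fee * fp
  12 * monthly_fee + tft_fee * (1 - visit_cost_reduction) + fp_part
}
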