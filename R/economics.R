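#' Discount factor for a model cycle
#'
#' `(1 + rate)^(-cycle)`; cycle 0 (the entry year) is undiscounted.
#'
#' @param cycle Cycle index, integer `>= 0`.
#' @param rate Annual discount rate, `> -1`.
#' @return Numeric discount factor(s).
#' @export
#' @examples
#' discount_factor(10, 0.045)
discount_factor <- function(cycle, rate) {
  stopifnot(rate > -1)
  (1 + rate)^(-cycle)
}

arm_summary <- function(x) {
  if (inherits(x, "thyrocea_cohort")) {
    list(cost = x$mean_cost, qaly = x$mean_qaly, se_cost = x$se_cost,
         se_qaly = x$se_qaly, n = x$n, seed = x$seed,
         cost_vec = x$cost, qaly_vec = x$qaly)
  } else if (inherits(x, "thyrocea_expectation")) {
    list(cost = x$cost, qaly = x$qaly, se_cost = NA_real_, se_qaly = NA_real_,
         n = NA_integer_, seed = NA_integer_, cost_vec = NULL, qaly_vec = NULL)
  } else {
    stop("expected a thyrocea_cohort or thyrocea_expectation", call. = FALSE)
  }
}

#' Cost-effectiveness comparison of two strategies
#'
#' Computes incremental cost (`delta_cost`), incremental effectiveness
#' (`delta_qaly`), the incremental cost-effectiveness ratio (ICER =
#' `delta_cost / delta_qaly`), per-person net monetary benefit (NMB =
#' `qaly * wtp - cost`) for each arm, the incremental NMB, and cohort totals
#' (per-person values scaled by the cohort size). Dominance is flagged
#' instead of an ICER when one arm is at least as effective and no more
#' costly (strictly better somewhere); `|delta_qaly| < 1e-9` flags the ICER
#' undefined. When both arms are microsimulation results of equal size run
#' with the same seed (common random numbers), incremental standard errors
#' use the paired per-patient differences.
#'
#' @param control,digital Results from [simulate_cohort()] or
#'   [cohort_expectation()].
#' @param economics Economics settings (a list with `wtp`; e.g.
#'   `config$economics`).
#' @param cohort_n Cohort size used for the cohort-total NMB rows (defaults
#'   to the microsimulation size, or 10,000 for oracle inputs).
#' @return A list of class `thyrocea_ce`.
#' @export
#' @examples
#' cfg <- default_config(cohort = list(n = 300))
#' ce <- compare_arms(simulate_cohort(cfg, "control", seed = 7),
#'                    simulate_cohort(cfg, "digital", seed = 7),
#'                    cfg$economics)
#' ce$icer
compare_arms <- function(control, digital, economics, cohort_n = NULL) {
  ctl <- arm_summary(control)
  dig <- arm_summary(digital)
  wtp <- economics$wtp
  dC <- dig$cost - ctl$cost
  dE <- dig$qaly - ctl$qaly

  paired <- !is.null(ctl$cost_vec) && !is.null(dig$cost_vec) &&
    ctl$n == dig$n && identical(ctl$seed, dig$seed)
  if (paired) {
    se_dC <- stats::sd(dig$cost_vec - ctl$cost_vec) / sqrt(ctl$n)
    se_dE <- stats::sd(dig$qaly_vec - ctl$qaly_vec) / sqrt(ctl$n)
  } else if (!is.na(ctl$se_cost) && !is.na(dig$se_cost)) {
    se_dC <- sqrt(ctl$se_cost^2 + dig$se_cost^2)
    se_dE <- sqrt(ctl$se_qaly^2 + dig$se_qaly^2)
  } else {
    se_dC <- se_dE <- NA_real_
  }

  digital_dominant <- dC <= 0 && dE >= 0 && (dC < 0 || dE > 0)
  digital_dominated <- dC >= 0 && dE <= 0 && (dC > 0 || dE < 0)
  icer_undefined <- abs(dE) < 1e-9
  icer <- if (digital_dominant || digital_dominated || icer_undefined) {
    NA_real_
  } else {
    dC / dE
  }

  n_tot <- cohort_n %||% (if (!is.na(ctl$n)) ctl$n else 10000L)
  nmb_control <- ctl$qaly * wtp - ctl$cost
  nmb_digital <- dig$qaly * wtp - dig$cost
  structure(list(
    cost_control = ctl$cost, cost_digital = dig$cost,
    qaly_control = ctl$qaly, qaly_digital = dig$qaly,
    se_cost_control = ctl$se_cost, se_cost_digital = dig$se_cost,
    se_qaly_control = ctl$se_qaly, se_qaly_digital = dig$se_qaly,
    delta_cost = dC, delta_qaly = dE, se_delta_cost = se_dC,
    se_delta_qaly = se_dE, icer = icer,
    digital_dominant = digital_dominant,
    digital_dominated = digital_dominated,
    icer_undefined = icer_undefined,
    nmb_control = nmb_control, nmb_digital = nmb_digital,
    inmb = dE * wtp - dC,
    nmb_control_cohort = nmb_control * n_tot,
    nmb_digital_cohort = nmb_digital * n_tot,
    inmb_cohort = (dE * wtp - dC) * n_tot,
    wtp = wtp, paired = paired, n = n_tot
  ), class = "thyrocea_ce")
}

#' @export
print.thyrocea_ce <- function(x, ...) {
  cat("<thyrocea_ce>  (control vs digital)\n")
  cat(sprintf("  cost/person:  %10.2f   %10.2f   (delta %.2f)\n",
              x$cost_control, x$cost_digital, x$delta_cost))
  cat(sprintf("  QALY/person:  %10.2f   %10.2f   (delta %.4f)\n",
              x$qaly_control, x$qaly_digital, x$delta_qaly))
  if (x$digital_dominant) {
    cat("  digital arm dominant (cheaper, at least as effective)\n")
  } else if (x$digital_dominated) {
    cat("  digital arm dominated\n")
  } else if (x$icer_undefined) {
    cat("  ICER undefined (|delta QALY| < 1e-9)\n")
  } else {
    cat(sprintf("  ICER: %.2f per QALY gained\n", x$icer))
  }
  cat(sprintf("  NMB/person at WTP %s: %.2f vs %.2f; INMB %.2f\n",
              format(x$wtp, big.mark = ","), x$nmb_control, x$nmb_digital,
              x$inmb))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of probabilistic
#' sensitivity analysis draws in which the digital arm has positive
#' incremental net monetary benefit (`wtp * delta_qaly - delta_cost > 0`).
#'
#' @param draws A `thyrocea_psa` from [run_psa()], or a data frame with
#'   columns `dC` and `dE`.
#' @param wtp_grid Vector of willingness-to-pay values (must be non-empty).
#' @return A data frame with columns `wtp` and `prob_cost_effective`.
#' @export
ceac <- function(draws, wtp_grid) {
  if (length(wtp_grid) < 1) stop("wtp_grid must be non-empty", call. = FALSE)
  d <- if (inherits(draws, "thyrocea_psa")) draws$draws else draws
  if (nrow(d) < 1) stop("need at least one PSA draw", call. = FALSE)
  prob <- vapply(wtp_grid, function(w) mean(w * d$dE - d$dC > 0), numeric(1))
  data.frame(wtp = wtp_grid, prob_cost_effective = prob)
}
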