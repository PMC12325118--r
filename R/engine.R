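# Internal expanded state space.
#
# The semi-Markov rules (a 2-year ATD course, a 5-year relapse window, and
# "ever relapsed" memory needed by the lifetime classification) are made
# Markov by tunnel expansion.  Alive states, indexed 1..S:
#   1..k                 initial ATD course, year 1..k
#   k+1 .. k+m           remission tunnel year 1..m, never relapsed
#   k+m+1 .. k+2m        remission tunnel year 1..m, previously relapsed
#   k+2m+1, k+2m+2       long-term remission (never / previously relapsed)
#   k+2m+3               relapse on long-term ATD
#   k+2m+4, k+2m+5       hypothyroid (never / previously relapsed)
# The complication tag (none or one of six) is a second, sticky coordinate.
# Death is absorbing and accrues nothing.
#
# Event order within a cycle (identical in the microsimulation and in the
# deterministic oracle, so their expectations agree exactly):
#   1. accrue cost and utility for the state occupied at cycle start,
#      discounted by (1+r)^(-cycle);
#   2. death at the age-specific probability;
#   3. survivors in active-disease states may acquire a complication
#      (effective from the next cycle);
#   4. state transition.

build_engine_params <- function(config, arm = c("control", "digital")) {
  arm <- match.arg(arm)
  pv <- function(n) param_value(config, n)
  st <- config$structure
  iv <- config$intervention
  k <- as.integer(st$atd_course_years)
  m <- as.integer(st$remission_window_years)
  S <- k + 2L * m + 5L
  i_R0 <- k + 1L
  i_R1 <- k + m + 1L
  i_LTR0 <- k + 2L * m + 1L
  i_LTR1 <- k + 2L * m + 2L
  i_REL <- k + 2L * m + 3L
  i_HYP0 <- k + 2L * m + 4L
  i_HYP1 <- k + 2L * m + 5L

  annualised <- function(name) {
    i <- match(name, config$parameters$name)
    h <- config$parameters$horizon_years[i]
    b <- config$parameters$base[i]
    if (is.na(h) || h == 1) b else prob_to_annual(b, h)
  }
  p_fail <- annualised("p_atd_failure")
  p_hypo <- annualised("p_hypothyroidism")
  p_rel <- annualised("p_relapse")
  tao_w <- min(as.integer(st$tao_window_years), k)
  p_tao_yr <- if (tao_w > 0) prob_to_annual(pv("p_tao"), tao_w) else 0
  p_comp <- c(pv("p_atrial_fibrillation"), pv("p_heart_failure"),
              pv("p_osteoporosis"), pv("p_fracture"), pv("p_thyroid_cancer"))

  sens <- pv("sens_digital")
  spec <- pv("spec_digital")
  fee <- pv("monthly_fee")
  sens_ref <- iv$sensitivity_reference %||% 0.8713
  aversion <- 0
  srp <- st$subsequent_remission_prob
  if (arm == "digital") {
    aversion <- (1 - iv$theta_p) * sens / sens_ref
    if (aversion < 0 || aversion > 1) {
      warning("relapse-aversion probability clamped into [0,1]", call. = FALSE)
      aversion <- min(1, max(0, aversion))
    }
    srp <- st$subsequent_remission_prob * iv$theta_r
    if (srp > 1) {
      warning("subsequent remission probability clamped to 1", call. = FALSE)
      srp <- 1
    }
  }

  # per-state annual cost, utility, excess-mortality hazard ratio
  state_cost <- numeric(S)
  state_cost[1L] <- pv("c_acute_care")
  if (k > 1) state_cost[2:k] <- pv("c_long_term_atd")
  state_cost[i_REL] <- pv("c_long_term_atd")
  state_cost[c(i_HYP0, i_HYP1)] <- pv("c_hypothyroid")

  state_util <- numeric(S)
  state_util[1:k] <- pv("u_atd")
  state_util[i_REL] <- pv("u_atd")
  state_util[i_R0:(i_R0 + m - 1L)] <- pv("u_remission")
  state_util[i_R1:(i_R1 + m - 1L)] <- pv("u_remission")
  state_util[c(i_LTR0, i_LTR1)] <- pv("u_remission")
  state_util[c(i_HYP0, i_HYP1)] <- pv("u_hypothyroid")

  base_label <- character(S)
  base_label[1:k] <- "on_ATD_initial"
  base_label[c(i_R0:(i_R0 + m - 1L), i_R1:(i_R1 + m - 1L))] <- "remission"
  base_label[c(i_LTR0, i_LTR1)] <- "long_term_remission"
  base_label[i_REL] <- "relapse_on_long_term_ATD"
  base_label[c(i_HYP0, i_HYP1)] <- "hypothyroid"
  hr_state <- unname(st$excess_mortality[base_label])
  hr_state[is.na(hr_state)] <- 1

  tft <- pv("c_tft_visit")
  extra <- st$extra_annual_cost[[arm]] %||% 0
  if (arm == "control") {
    mon_fixed <- tft + extra
    fp_prob <- numeric(S)
  } else {
    mon_fixed <- 12 * fee + tft * (1 - iv$visit_cost_reduction) + extra
    fp_prob <- numeric(S)
    nonhyper <- c(i_R0:(i_R0 + m - 1L), i_R1:(i_R1 + m - 1L),
                  i_LTR0, i_LTR1, i_HYP0, i_HYP1)
    fp_prob[nonhyper] <- 1 - spec
  }

  comp_cost <- c(0, pv("c_tao"), pv("c_atrial_fibrillation"),
                 pv("c_heart_failure"), pv("c_osteoporosis"),
                 pv("c_fracture"), pv("c_thyroid_cancer"))
  comp_util <- c(1, pv("u_tao"), pv("u_atrial_fibrillation"),
                 pv("u_heart_failure"), pv("u_osteoporosis"),
                 pv("u_fracture"), pv("u_thyroid_cancer"))

  lt <- config_life_table(config)
  qx <- lt$qx[order(lt$age)]

  # classification lookup: rows = comp absent / present, cols = state
  ever_rel <- c(i_R1:(i_R1 + m - 1L), i_LTR1, i_REL, i_HYP1)
  preds <- list(
    complication = function(has_comp, s) rep(has_comp, length(s)),
    hypothyroid = function(has_comp, s) s %in% c(i_HYP0, i_HYP1),
    long_term_remission = function(has_comp, s) s %in% c(i_LTR0, i_LTR1),
    relapse_on_long_term_ATD = function(has_comp, s) s %in% ever_rel
  )
  class_lookup <- matrix(match("other", .CLASS_LABELS), 2L, S)
  for (lab in rev(st$classification_priority)) {
    for (row in 1:2) {
      hit <- preds[[lab]](row == 2L, seq_len(S))
      class_lookup[row, hit] <- match(lab, .CLASS_LABELS)
    }
  }

  list(
    arm = arm, k = k, m = m, S = S, tao_w = tao_w,
    i_R0 = i_R0, i_R1 = i_R1, i_LTR0 = i_LTR0, i_LTR1 = i_LTR1,
    i_REL = i_REL, i_HYP0 = i_HYP0, i_HYP1 = i_HYP1,
    p_fail = p_fail, p_hypo = p_hypo, p_rel = p_rel,
    p_tao_yr = p_tao_yr, p_comp = p_comp,
    aversion = aversion, srp = srp,
    state_cost = state_cost, state_util = state_util,
    mon_fixed = mon_fixed, fp_prob = fp_prob, fp_cost = tft,
    comp_cost = comp_cost, comp_util = comp_util,
    hr_state = hr_state, base_label = base_label,
    qx = qx, v = 1 / (1 + config$economics$discount_rate),
    start_age = as.integer(config$cohort$start_age),
    max_cycles = as.integer(config$cohort$max_cycles),
    class_lookup = class_lookup
  )
}

#' Simulate a patient cohort through the disease course
#'
#' Patient-level discrete-time simulation: every patient enters at the cohort
#' start age on initial antithyroid-drug (ATD) therapy and is advanced through
#' annual cycles until death or the cycle horizon, accruing discounted cost
#' and quality-adjusted life years (QALYs) at each cycle start. Random-number
#' consumption follows a fixed per-cycle schedule (one stream per decision
#' channel), so running the control and digital arms with the same `seed`
#' uses common random numbers: patient `i` experiences identical luck in both
#' arms wherever the arms do not differ.
#'
#' @param config A model configuration, see [default_config()].
#' @param arm `"control"` (usual care) or `"digital"` (digital monitoring).
#' @param n Number of simulated patients; defaults to `config$cohort$n`.
#' @param seed Integer RNG seed; the same seed reproduces the result
#'   bit-for-bit.
#' @param trace If `TRUE`, keep the per-cycle state label of every patient
#'   (memory: `n * max_cycles` integers).
#' @return A list of class `thyrocea_cohort`: per-patient discounted `cost`,
#'   `qaly` and undiscounted life years `ly`, a lifetime `classification`
#'   factor, means with Monte-Carlo standard errors, and classification
#'   shares.
#' @seealso [cohort_expectation()] for the exact expectation of the same
#'   process, [compare_arms()] for cost-effectiveness statistics.
#' @export
#' @examples
#' cfg <- default_config(cohort = list(n = 200))
#' res <- simulate_cohort(cfg, "control", seed = 1)
#' res$mean_qaly
simulate_cohort <- function(config, arm = c("control", "digital"),
                            n = config$cohort$n, seed = 1L, trace = FALSE) {
  arm <- match.arg(arm)
  stopifnot(n >= 1)
  ep <- build_engine_params(config, arm)
  set.seed(as.integer(seed))
  state <- rep(1L, n)
  alive <- rep(TRUE, n)
  comp <- rep(0L, n)
  cost <- qaly <- ly <- numeric(n)
  traj <- if (trace) matrix(NA_integer_, n, ep$max_cycles) else NULL

  for (t in 0:(ep$max_cycles - 1L)) {
    if (!any(alive)) break
    # channels: 1 death, 2 transition, 3 detection, 4 hypothyroidism,
    # 5-10 complications (TAO, AF, HF, osteoporosis, fracture, cancer), 11 FP visit
    D <- matrix(runif(n * 11L), n, 11L)
    idx <- which(alive)
    s <- state[idx]
    cm <- comp[idx]
    vt <- ep$v^t
    if (trace) traj[cbind(idx, t + 1L)] <- s

    cst <- ep$state_cost[s] + ep$comp_cost[cm + 1L] + ep$mon_fixed
    fp <- ep$fp_prob[s]
    if (any(fp > 0)) cst <- cst + ep$fp_cost * (D[idx, 11L] < fp)
    cost[idx] <- cost[idx] + vt * cst
    qaly[idx] <- qaly[idx] + vt * pmin(ep$state_util[s], ep$comp_util[cm + 1L])
    ly[idx] <- ly[idx] + 1

    age <- ep$start_age + t
    q <- 1 - (1 - ep$qx[min(age, 110L) + 1L])^ep$hr_state[s]
    die <- D[idx, 1L] < q
    alive[idx[die]] <- FALSE
    liv <- idx[!die]
    if (!length(liv)) next

    s <- state[liv]
    can <- comp[liv] == 0L & (s <= ep$k | s == ep$i_REL)
    if (any(can)) {
      j <- liv[can]
      sj <- s[can]
      newc <- integer(length(j))
      newc[D[j, 10L] < ep$p_comp[5L]] <- 6L
      newc[D[j, 9L] < ep$p_comp[4L]] <- 5L
      newc[D[j, 8L] < ep$p_comp[3L]] <- 4L
      newc[D[j, 7L] < ep$p_comp[2L]] <- 3L
      newc[D[j, 6L] < ep$p_comp[1L]] <- 2L
      newc[sj <= ep$tao_w & D[j, 5L] < ep$p_tao_yr] <- 1L
      comp[j] <- newc
    }

    u_trans <- D[liv, 2L]
    u_det <- D[liv, 3L]
    u_hyp <- D[liv, 4L]
    ns <- s

    isA <- s <= ep$k
    if (any(isA)) {
      to_hyp <- isA & (u_trans < ep$p_fail | u_hyp < ep$p_hypo)
      adv <- isA & !to_hyp
      ns[to_hyp] <- ep$i_HYP0
      ns[adv] <- ifelse(s[adv] < ep$k, s[adv] + 1L, ep$i_R0)
    }

    isR <- s > ep$k & s <= ep$k + 2L * ep$m
    if (any(isR)) {
      flag1 <- s > ep$k + ep$m
      ev <- isR & u_trans < ep$p_rel
      avert <- ev & u_det < ep$aversion
      to_rel <- ev & !avert
      advR <- isR & !ev
      ns[avert] <- ifelse(flag1[avert], ep$i_R1, ep$i_R0)
      ns[to_rel] <- ep$i_REL
      rpos <- s - ep$k - ifelse(flag1, ep$m, 0L)
      lastR <- advR & rpos == ep$m
      midR <- advR & rpos < ep$m
      ns[midR] <- s[midR] + 1L
      ns[lastR] <- ifelse(flag1[lastR], ep$i_LTR1, ep$i_LTR0)
    }

    isREL <- s == ep$i_REL
    if (any(isREL)) {
      to_hyp <- isREL & u_hyp < ep$p_hypo
      to_rem <- isREL & !to_hyp & u_trans < ep$srp
      ns[to_hyp] <- ep$i_HYP1
      ns[to_rem] <- ep$i_R1
    }
    state[liv] <- as.integer(ns)
  }

  cls_idx <- ep$class_lookup[cbind((comp > 0L) + 1L, state)]
  classification <- factor(.CLASS_LABELS[cls_idx], levels = .CLASS_LABELS)
  res <- list(
    arm = arm, n = n, seed = as.integer(seed),
    cost = cost, qaly = qaly, ly = ly,
    alive_at_end = alive,
    complication = factor(c("none", .COMPLICATIONS)[comp + 1L],
                          levels = c("none", .COMPLICATIONS)),
    classification = classification,
    mean_cost = mean(cost), se_cost = stats::sd(cost) / sqrt(n),
    mean_qaly = mean(qaly), se_qaly = stats::sd(qaly) / sqrt(n),
    class_shares = prop.table(table(classification))
  )
  if (trace) {
    res$trajectory <- traj
    res$trajectory_labels <- ep$base_label
  }
  structure(res, class = "thyrocea_cohort")
}

#' @export
print.thyrocea_cohort <- function(x, ...) {
  cat(sprintf("<thyrocea_cohort> %s arm, n = %d, seed = %d\n", x$arm, x$n, x$seed))
  cat(sprintf("  discounted cost/person:  %10.2f (SE %.2f)\n", x$mean_cost, x$se_cost))
  cat(sprintf("  discounted QALY/person:  %10.4f (SE %.4f)\n", x$mean_qaly, x$se_qaly))
  sh <- 100 * x$class_shares
  cat("  lifetime classification (%):\n")
  for (nm in names(sh)) cat(sprintf("    %-26s %6.2f\n", nm, sh[[nm]]))
  invisible(x)
}

#' Classify a simulated patient trajectory
#'
#' Assigns the single lifetime label used in cohort summaries: the first
#' category in `priority` that the patient ever entered or experienced, from
#' `complication` (any acquired complication), `hypothyroid`,
#' `long_term_remission` and `relapse_on_long_term_ATD`; patients matching
#' none (e.g. dying during the initial ATD course) are `"other"`.
#'
#' @param states Character vector of visited health-state labels.
#' @param complication A complication label, or `NA`/`"none"` if none was
#'   acquired.
#' @param priority Classification priority order.
#' @return A single classification label.
#' @export
#' @examples
#' classify_trajectory(c("on_ATD_initial", "remission", "long_term_remission"))
classify_trajectory <- function(states, complication = NA,
                                priority = c("complication", "hypothyroid",
                                             "long_term_remission",
                                             "relapse_on_long_term_ATD")) {
  has <- c(
    complication = !is.na(complication) && complication != "none",
    hypothyroid = "hypothyroid" %in% states,
    long_term_remission = "long_term_remission" %in% states,
    relapse_on_long_term_ATD = "relapse_on_long_term_ATD" %in% states
  )
  for (lab in priority) if (isTRUE(has[[lab]])) return(lab)
  "other"
}
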