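# Build the one-cycle base-state transition matrix T[from, to] (conditional on
# survival).  Must mirror simulate_cohort()'s sampling logic exactly.
build_transition_matrix <- function(ep) {
  S <- ep$S
  Tm <- matrix(0, S, S)
  p_exit_atd <- ep$p_fail + (1 - ep$p_fail) * ep$p_hypo
  for (i in seq_len(ep$k)) {
    Tm[i, ep$i_HYP0] <- p_exit_atd
    nxt <- if (i < ep$k) i + 1L else ep$i_R0
    Tm[i, nxt] <- Tm[i, nxt] + 1 - p_exit_atd
  }
  for (f in 0:1) {
    r1 <- if (f == 0) ep$i_R0 else ep$i_R1
    ltr <- if (f == 0) ep$i_LTR0 else ep$i_LTR1
    for (j in seq_len(ep$m)) {
      s <- ep$k + f * ep$m + j
      Tm[s, ep$i_REL] <- Tm[s, ep$i_REL] + ep$p_rel * (1 - ep$aversion)
      Tm[s, r1] <- Tm[s, r1] + ep$p_rel * ep$aversion
      nxt <- if (j < ep$m) s + 1L else ltr
      Tm[s, nxt] <- Tm[s, nxt] + 1 - ep$p_rel
    }
  }
  Tm[ep$i_REL, ep$i_HYP1] <- ep$p_hypo
  Tm[ep$i_REL, ep$i_R1] <- (1 - ep$p_hypo) * ep$srp
  Tm[ep$i_REL, ep$i_REL] <- (1 - ep$p_hypo) * (1 - ep$srp)
  Tm[ep$i_LTR0, ep$i_LTR0] <- 1
  Tm[ep$i_LTR1, ep$i_LTR1] <- 1
  Tm[ep$i_HYP0, ep$i_HYP0] <- 1
  Tm[ep$i_HYP1, ep$i_HYP1] <- 1
  Tm
}

# Per-state probabilities of acquiring each complication tag in one cycle
# (first-drawn-wins over independent annual events, ties broken in listed
# order: TAO, AF, HF, osteoporosis, fracture, thyroid cancer).
build_comp_acquisition <- function(ep) {
  ptag <- matrix(0, ep$S, 6L)
  active <- c(seq_len(ep$k), ep$i_REL)
  for (s in active) {
    p_tao <- if (s <= ep$tao_w) ep$p_tao_yr else 0
    probs <- c(p_tao, ep$p_comp)
    stay <- 1
    for (j in seq_along(probs)) {
      ptag[s, j] <- stay * probs[j]
      stay <- stay * (1 - probs[j])
    }
  }
  ptag
}

#' Exact expected trajectory of the cohort (deterministic oracle)
#'
#' Computes the exact expectation of the same discrete-time process that
#' [simulate_cohort()] samples, by propagating the state-occupancy
#' distribution over the tunnel-expanded state space (initial-ATD years,
#' remission-window years with relapse memory, long-term remission, relapse
#' on long-term ATD, hypothyroid, each crossed with the sticky complication
#' tag). Microsimulation means converge to these values as `n` grows; the
#' package's test suite holds the two within three Monte-Carlo standard
#' errors.
#'
#' Deterministic analyses (one-way sensitivity, the subscription-fee
#' threshold, calibration) run on this oracle so that parameter rankings and
#' root-finding are free of Monte-Carlo noise.
#'
#' @inheritParams simulate_cohort
#' @return A list of class `thyrocea_expectation`: expected discounted `cost`
#'   and `qaly` per person, expected undiscounted life years `ly`, lifetime
#'   classification shares, per-cycle occupancy by health-state label (plus
#'   dead), the per-cycle alive fraction, and the per-cycle probability-mass
#'   total (`conservation`, identically 1).
#' @export
#' @examples
#' ex <- cohort_expectation(default_config(), "control")
#' ex$qaly
#' ex$class_shares
cohort_expectation <- function(config, arm = c("control", "digital")) {
  arm <- match.arg(arm)
  ep <- build_engine_params(config, arm)
  S <- ep$S
  Tt <- t(build_transition_matrix(ep))
  ptag <- build_comp_acquisition(ep)
  active_rows <- which(rowSums(ptag) > 0)

  dist <- matrix(0, S, 7L)
  dist[1L, 1L] <- 1
  dead_by_class <- setNames(numeric(5L), .CLASS_LABELS)

  cls_mat <- cbind(ep$class_lookup[1L, ], matrix(ep$class_lookup[2L, ], S, 6L))
  cost_s <- ep$state_cost + ep$mon_fixed + ep$fp_prob * ep$fp_cost
  util_mat <- pmin(matrix(ep$state_util, S, 7L),
                   matrix(ep$comp_util, S, 7L, byrow = TRUE))

  labels <- c(unique(ep$base_label), "dead")
  occupancy <- matrix(0, ep$max_cycles, length(labels),
                      dimnames = list(NULL, labels))
  alive_frac <- conservation <- numeric(ep$max_cycles)
  exp_cost <- exp_qaly <- exp_ly <- 0

  for (t in 0:(ep$max_cycles - 1L)) {
    vt <- ep$v^t
    row_mass <- rowSums(dist)
    alive_frac[t + 1L] <- sum(row_mass)
    conservation[t + 1L] <- sum(row_mass) + sum(dead_by_class)
    occ <- tapply(row_mass, ep$base_label, sum)
    occupancy[t + 1L, names(occ)] <- occ
    occupancy[t + 1L, "dead"] <- sum(dead_by_class)

    exp_cost <- exp_cost +
      vt * (sum(row_mass * cost_s) + sum(colSums(dist) * ep$comp_cost))
    exp_qaly <- exp_qaly + vt * sum(dist * util_mat)
    exp_ly <- exp_ly + sum(row_mass)

    age <- ep$start_age + t
    q_s <- 1 - (1 - ep$qx[min(age, 110L) + 1L])^ep$hr_state
    death_mass <- dist * q_s
    for (l in seq_len(5L)) {
      dead_by_class[l] <- dead_by_class[l] + sum(death_mass[cls_mat == l])
    }
    dist <- dist * (1 - q_s)

    if (length(active_rows)) {
      moved <- dist[active_rows, 1L] * ptag[active_rows, , drop = FALSE]
      dist[active_rows, 1L] <- dist[active_rows, 1L] - rowSums(moved)
      dist[active_rows, 2:7] <- dist[active_rows, 2:7] + moved
    }
    dist <- Tt %*% dist
  }

  shares <- dead_by_class
  for (l in seq_len(5L)) shares[l] <- shares[l] + sum(dist[cls_mat == l])

  structure(list(
    arm = arm, cost = exp_cost, qaly = exp_qaly, ly = exp_ly,
    class_shares = shares,
    occupancy = occupancy, alive = alive_frac, conservation = conservation,
    final_alive = sum(dist)
  ), class = "thyrocea_expectation")
}

#' @export
print.thyrocea_expectation <- function(x, ...) {
  cat(sprintf("<thyrocea_expectation> %s arm\n", x$arm))
  cat(sprintf("  expected discounted cost/person: %10.2f\n", x$cost))
  cat(sprintf("  expected discounted QALY/person: %10.4f\n", x$qaly))
  cat(sprintf("  expected life years:             %10.2f\n", x$ly))
  sh <- 100 * x$class_shares
  cat("  lifetime classification (%):\n")
  for (nm in names(sh)) cat(sprintf("    %-26s %6.2f\n", nm, sh[[nm]]))
  invisible(x)
}
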