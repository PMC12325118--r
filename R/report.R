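#' Run the base-case analysis
#'
#' Simulates both arms with common random numbers and computes the
#' cost-effectiveness comparison; optionally also evaluates the
#' deterministic oracle for both arms.
#'
#' @param config A (calibrated) model configuration.
#' @param seed Integer seed shared by both arms (common random numbers).
#' @param n Patients per arm.
#' @param oracle If `TRUE`, attach `cohort_expectation()` results.
#' @return A list of class `thyrocea_run` with elements `control`,
#'   `digital`, `ce`, and (optionally) `oracle_control`, `oracle_digital`,
#'   `oracle_ce`.
#' @export
run_base_case <- function(config, seed = 1L, n = config$cohort$n,
                          oracle = FALSE) {
  ctl <- simulate_cohort(config, "control", n = n, seed = seed)
  dig <- simulate_cohort(config, "digital", n = n, seed = seed)
  out <- list(control = ctl, digital = dig,
              ce = compare_arms(ctl, dig, config$economics))
  if (oracle) {
    out$oracle_control <- cohort_expectation(config, "control")
    out$oracle_digital <- cohort_expectation(config, "digital")
    out$oracle_ce <- compare_arms(out$oracle_control, out$oracle_digital,
                                  config$economics, cohort_n = n)
  }
  structure(out, class = "thyrocea_run")
}

#' @export
print.thyrocea_run <- function(x, ...) {
  cat(sprintf("<thyrocea_run> n = %d per arm, seed = %d\n",
              x$control$n, x$control$seed))
  shares <- rbind(control = 100 * as.numeric(x$control$class_shares),
                  digital = 100 * as.numeric(x$digital$class_shares))
  colnames(shares) <- names(x$control$class_shares)
  cat("  lifetime classification shares (%):\n")
  print(round(shares, 2))
  print(x$ce)
  invisible(x)
}

#' Visit-cost-reduction scenario analysis
#'
#' Re-runs the base case with the digital arm's scheduled monitoring-visit
#' cost reduced by each fraction in `reductions` (the control arm is
#' unchanged and shared across scenarios).
#'
#' @param config A (calibrated) model configuration.
#' @param reductions Fractions in `[0, 1]`.
#' @param seed Common-random-number seed.
#' @param n Patients per arm.
#' @return A data frame with one row per scenario: per-person discounted
#'   costs and QALYs for both arms, incremental values, and the ICER.
#' @export
run_scenarios <- function(config, reductions = c(0, 0.10, 0.20, 0.30),
                          seed = 1L, n = config$cohort$n) {
  ctl <- simulate_cohort(config, "control", n = n, seed = seed)
  rows <- lapply(reductions, function(red) {
    cfg <- config
    cfg$intervention$visit_cost_reduction <- red
    dig <- simulate_cohort(cfg, "digital", n = n, seed = seed)
    ce <- compare_arms(ctl, dig, config$economics)
    data.frame(visit_cost_reduction = red,
               cost_control = ce$cost_control, cost_digital = ce$cost_digital,
               qaly_control = ce$qaly_control, qaly_digital = ce$qaly_digital,
               delta_cost = ce$delta_cost, delta_qaly = ce$delta_qaly,
               icer = ce$icer)
  })
  do.call(rbind, rows)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_config(config, f)
  unname(tools::md5sum(f))
}

#' Write a run manifest
#'
#' Every output directory written by the command-line interface carries one
#' manifest: the configuration hash, seed, subcommand, timestamp, package
#' version and output file list -- enough to reproduce the run.
#'
#' @param config The configuration used.
#' @param seed The seed used.
#' @param subcommand Name of the analysis that was run.
#' @param outputs Character vector of files written.
#' @param dir Output directory; the manifest is written to
#'   `dir/manifest.json`.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(config, seed, subcommand, outputs, dir) {
  manifest <- list(
    package = "thyrocea",
    version = as.character(utils::packageVersion("thyrocea")),
    subcommand = subcommand,
    seed = as.integer(seed),
    config_md5 = config_hash(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Summarise a run as a plain list (for JSON output)
#'
#' @param run A `thyrocea_run`.
#' @return A nested list of numeric summaries.
#' @export
run_summary <- function(run) {
  ce <- run$ce
  list(
    n = run$control$n,
    seed = run$control$seed,
    control = list(
      cost = ce$cost_control, qaly = ce$qaly_control,
      shares = as.list(100 * run$control$class_shares)
    ),
    digital = list(
      cost = ce$cost_digital, qaly = ce$qaly_digital,
      shares = as.list(100 * run$digital$class_shares)
    ),
    delta_cost = ce$delta_cost,
    delta_qaly = ce$delta_qaly,
    icer = ce$icer,
    digital_dominant = ce$digital_dominant,
    nmb_control = ce$nmb_control,
    nmb_digital = ce$nmb_digital,
    inmb = ce$inmb,
    wtp = ce$wtp
  )
}

#' Tornado diagram of the one-way sensitivity analysis
#'
#' @param tornado A `thyrocea_tornado` from [one_way_dsa()].
#' @param top Number of widest parameters to show.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, top = 12L) {
  d <- utils::head(as.data.frame(tornado), top)
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  base <- attr(tornado, "base_icer")
  ggplot2::ggplot(d) +
    ggplot2::geom_segment(ggplot2::aes(x = icer_low, xend = icer_high,
                                       y = parameter, yend = parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(x = "ICER (USD per QALY)", y = NULL,
                  title = "One-way sensitivity of the ICER",
                  subtitle = sprintf("dashed line: base case %.0f", base)) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param ceac_df Output of [ceac()].
#' @param wtp Willingness-to-pay threshold to mark.
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_df, wtp = NULL) {
  p <- ggplot2::ggplot(ceac_df,
                       ggplot2::aes(x = wtp, y = prob_cost_effective)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (USD per QALY)",
                  y = "P(digital arm cost-effective)",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) p <- p + ggplot2::geom_vline(xintercept = wtp, linetype = 2)
  p
}

#' Incremental cost-effectiveness scatterplot
#'
#' @param psa A `thyrocea_psa`.
#' @param wtp Willingness-to-pay threshold drawn as a line through the
#'   origin.
#' @return A ggplot object.
#' @export
plot_ice <- function(psa, wtp = 32255) {
  d <- psa$draws
  ggplot2::ggplot(d, ggplot2::aes(x = dE, y = dC)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.8, colour = "steelblue") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey40") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (USD)",
                  title = "Incremental cost-effectiveness scatter") +
    ggplot2::theme_minimal()
}
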