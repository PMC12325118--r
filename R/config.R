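#' Default model configuration
#'
#' Builds the fully specified model configuration: health states, complication
#' types, the parameter table ([default_parameters()]), economics settings
#' (4.5% discount rate, willingness-to-pay US $32,255/QALY), the structural
#' wiring of the disease course, the intervention block (digital monitor test
#' characteristics, US $30/month subscription), the cohort definition (10,000
#' patients entering at age 40, 70 annual cycles) and the synthetic
#' Gompertz-Makeham mortality model.
#'
#' Structural wiring (all config-exposed):
#' * Entry on antithyroid drugs (ATD) for `atd_course_years` (2) cycles;
#'   acute-care cost in year 1, ATD utility 0.86 while treated.
#' * ATD failure (5% over 1.5 y, annualised) routes to definitive therapy,
#'   modelled as the hypothyroid state.
#' * Completing the ATD course leads to remission; relapse risk (52.8% over
#'   3.73 y, annualised) applies for `remission_window_years` (5) years, after
#'   which the patient is in long-term remission (absorbing but for death).
#' * Relapse routes to long-term ATD; each year a `subsequent_remission_prob`
#'   chance of returning to remission (resetting the 5-year clock).
#' * ATD-induced hypothyroidism (2.9% over 10.2 y, annualised) applies in any
#'   ATD-taking state.
#' * Complications are acquired only in active-disease states (initial ATD,
#'   relapse on long-term ATD): thyroid-associated orbitopathy as a one-time
#'   25% risk spread over the first `tao_window_years` (2) treated years, the
#'   other five at their annual incidences; at most one complication per
#'   patient (first drawn wins, ties broken in listed order); a complication
#'   adds its annual cost and caps utility at the complication utility.
#' * Monitoring: the control arm accrues one full-fee thyroid function test
#'   (TFT) visit per alive year; the digital arm accrues the subscription plus
#'   a scheduled TFT visit (optionally reduced) plus false-positive visits,
#'   see [annual_monitoring_cost()].
#'
#' @param ... Named overrides merged into the default configuration (nested
#'   lists are merged recursively), e.g. `cohort = list(n = 1000)`.
#' @return A list of class `thyrocea_config`.
#' @export
#' @examples
#' cfg <- default_config(cohort = list(n = 500))
#' cfg$economics$wtp
default_config <- function(...) {
  config <- list(
    states = .STATE_LABELS,
    complication_types = .COMPLICATIONS,
    parameters = default_parameters(),
    economics = list(
      discount_rate = 0.045,
      wtp = 32255,
      currency_label = "USD 2022"
    ),
    structure = list(
      atd_course_years = 2L,
      remission_window_years = 5L,
      tao_window_years = 2L,
      subsequent_remission_prob = 0.05,
      classification_priority = c("complication", "hypothyroid",
                                  "long_term_remission",
                                  "relapse_on_long_term_ATD"),
      excess_mortality = c(on_ATD_initial = 1, remission = 1,
                           long_term_remission = 1,
                           relapse_on_long_term_ATD = 1, hypothyroid = 1),
      extra_annual_cost = list(control = 0, digital = 0)
    ),
    intervention = list(
      sensitivity = 0.8713,
      specificity = 0.8378,
      monthly_fee = 30,
      visit_cost_reduction = 0,
      theta_r = 1,
      theta_p = 1
    ),
    cohort = list(
      start_age = 40L,
      n = 10000L,
      max_cycles = 70L,
      cycle_length_years = 1
    ),
    mortality = list(
      type = "gompertz_makeham",
      makeham_a = 5e-4,
      gompertz_b = 3e-5,
      gompertz_eta = 0.095
    )
  )
  overrides <- list(...)
  if (length(overrides)) config <- modifyList(config, overrides)
  config <- structure(config, class = "thyrocea_config")
  validate_config(config)
}

#' Validate a model configuration
#'
#' Checks parameter-table invariants (low <= base <= high, probabilities and
#' utilities in `[0,1]`, non-negative costs, roles and distribution families
#' from the documented vocabularies), economics bounds (discount rate in
#' `[0, 0.2]`, positive willingness to pay), structural references
#' (classification priority and excess-mortality names must be known labels)
#' and cohort settings. Errors name every offending field.
#'
#' @param config A model configuration.
#' @return The validated configuration, invisibly classed `thyrocea_config`.
#' @export
validate_config <- function(config) {
  problems <- character()
  pars <- config$parameters
  req <- c("name", "role", "base", "low", "high", "horizon_years", "distribution")
  if (!all(req %in% names(pars))) {
    stop("parameter table must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(pars$name)) problems <- c(problems, "duplicated parameter names")
  bad <- pars$name[!(pars$low <= pars$base & pars$base <= pars$high)]
  if (length(bad)) problems <- c(problems,
    paste0("low <= base <= high violated: ", paste(bad, collapse = ", ")))
  unit <- pars$role %in% c("transition_probability", "test_characteristic", "utility")
  bad <- pars$name[unit & (pars$base < 0 | pars$base > 1 | pars$low < 0 | pars$high > 1)]
  if (length(bad)) problems <- c(problems,
    paste0("probability/utility outside [0,1]: ", paste(bad, collapse = ", ")))
  costs <- pars$role %in% c("annual_cost", "one_time_cost")
  bad <- pars$name[costs & pars$low < 0]
  if (length(bad)) problems <- c(problems,
    paste0("negative cost: ", paste(bad, collapse = ", ")))
  bad <- pars$name[!pars$role %in% .PARAM_ROLES]
  if (length(bad)) problems <- c(problems,
    paste0("unknown role: ", paste(bad, collapse = ", ")))
  bad <- pars$name[!pars$distribution %in% .PARAM_DISTS]
  if (length(bad)) problems <- c(problems,
    paste0("unknown distribution: ", paste(bad, collapse = ", ")))
  bad <- pars$name[!is.na(pars$horizon_years) & pars$horizon_years <= 0]
  if (length(bad)) problems <- c(problems,
    paste0("non-positive horizon: ", paste(bad, collapse = ", ")))

  ec <- config$economics
  if (ec$discount_rate < 0 || ec$discount_rate > 0.2) {
    problems <- c(problems, "economics$discount_rate outside [0, 0.2]")
  }
  if (ec$wtp <= 0) problems <- c(problems, "economics$wtp must be positive")

  st <- config$structure
  bad <- setdiff(st$classification_priority, .CLASS_LABELS)
  if (length(bad)) problems <- c(problems,
    paste0("unknown classification label: ", paste(bad, collapse = ", ")))
  bad <- setdiff(names(st$excess_mortality), .STATE_LABELS)
  if (length(bad)) problems <- c(problems,
    paste0("excess_mortality refers to unknown state: ", paste(bad, collapse = ", ")))
  if (st$atd_course_years < 1) problems <- c(problems, "atd_course_years must be >= 1")
  if (st$remission_window_years < 1) problems <- c(problems, "remission_window_years must be >= 1")
  if (st$subsequent_remission_prob < 0 || st$subsequent_remission_prob > 1) {
    problems <- c(problems, "subsequent_remission_prob outside [0,1]")
  }

  iv <- config$intervention
  for (nm in c("sensitivity", "specificity")) {
    if (iv[[nm]] < 0 || iv[[nm]] > 1) problems <- c(problems,
      paste0("intervention$", nm, " outside [0,1]"))
  }
  if (iv$monthly_fee < 0) problems <- c(problems, "intervention$monthly_fee must be >= 0")
  if (iv$visit_cost_reduction < 0 || iv$visit_cost_reduction > 1) {
    problems <- c(problems, "intervention$visit_cost_reduction outside [0,1]")
  }

  ch <- config$cohort
  if (ch$n < 1) problems <- c(problems, "cohort$n must be >= 1")
  if (ch$max_cycles * ch$cycle_length_years < 1) {
    problems <- c(problems, "cohort horizon shorter than one year")
  }
  if (ch$start_age < 0 || ch$start_age > 109) {
    problems <- c(problems, "cohort$start_age outside [0, 109]")
  }

  if (length(problems)) {
    stop("invalid model configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  invisible(structure(config, class = "thyrocea_config"))
}

#' Load a model configuration from a YAML file
#'
#' Reads a configuration written by [write_config()] (or authored by hand).
#' Any omitted block or parameter falls back to its default, so a partial file
#' overriding e.g. only the subscription fee is valid. The result is
#' validated; schema violations raise an error naming the offending fields.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `thyrocea_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  config <- unclass(default_config())
  if (!is.null(raw$parameters)) {
    tab <- config$parameters
    if (is.data.frame(raw$parameters)) {
      rows <- split(raw$parameters, seq_len(nrow(raw$parameters)))
    } else {
      rows <- raw$parameters
    }
    for (row in rows) {
      row <- as.list(row)
      if (is.null(row$name)) stop("parameter entry without a name", call. = FALSE)
      i <- match(row$name, tab$name)
      if (is.na(i)) {  # a new parameter row
        tab <- rbind(tab, data.frame(
          name = row$name,
          role = row$role %||% "annual_cost",
          base = as.numeric(row$base),
          low = as.numeric(row$low %||% (0.9 * as.numeric(row$base))),
          high = as.numeric(row$high %||% (1.1 * as.numeric(row$base))),
          horizon_years = as.numeric(row$horizon_years %||% NA_real_),
          distribution = row$distribution %||% "fixed",
          stringsAsFactors = FALSE))
      } else {
        for (col in c("role", "base", "low", "high", "horizon_years", "distribution")) {
          if (!is.null(row[[col]]) && !identical(row[[col]], "NA")) {
            tab[[col]][i] <- if (col %in% c("role", "distribution")) {
              as.character(row[[col]])
            } else as.numeric(row[[col]])
          }
        }
      }
    }
    raw$parameters <- NULL
    config$parameters <- tab
  }
  config <- modifyList(config, raw)
  # yaml flattens named numeric vectors to lists; restore
  config$structure$excess_mortality <- unlist(config$structure$excess_mortality)
  config$structure$classification_priority <-
    unlist(config$structure$classification_priority)
  config$states <- unlist(config$states)
  config$complication_types <- unlist(config$complication_types)
  validate_config(structure(config, class = "thyrocea_config"))
}

#' Write a model configuration to a YAML file
#'
#' The written file round-trips: `load_config(write_config(cfg, f))` equals
#' `cfg`.
#'
#' @param config A model configuration.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- unclass(config)
  out$parameters <- lapply(seq_len(nrow(config$parameters)), function(i) {
    row <- as.list(config$parameters[i, ])
    if (is.na(row$horizon_years)) row$horizon_years <- NULL
    row
  })
  out$structure$excess_mortality <- as.list(config$structure$excess_mortality)
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @export
print.thyrocea_config <- function(x, ...) {
  cat("<thyrocea_config>\n")
  cat(sprintf("  cohort: n=%d, start age %d, %d annual cycles\n",
              x$cohort$n, x$cohort$start_age, x$cohort$max_cycles))
  cat(sprintf("  economics: discount %.1f%%, WTP %s %s/QALY\n",
              100 * x$economics$discount_rate,
              format(x$economics$wtp, big.mark = ","), x$economics$currency_label))
  cat(sprintf("  intervention: sens %.4f, spec %.4f, fee %s/month, theta_r %.3f, theta_p %.3f\n",
              x$intervention$sensitivity, x$intervention$specificity,
              format(x$intervention$monthly_fee), x$intervention$theta_r,
              x$intervention$theta_p))
  cat(sprintf("  parameters: %d rows\n", nrow(x$parameters)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
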