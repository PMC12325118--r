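# Shared fixtures.  Calibration and the default life table are deterministic,
# so they are computed once per test run and reused.

.fixtures <- new.env(parent = emptyenv())

calibrated_cfg <- function() {
  if (is.null(.fixtures$calibrated)) {
    .fixtures$calibrated <- suppressWarnings(calibrate_model(default_config()))
  }
  .fixtures$calibrated
}

# a config small enough for quick microsimulation checks
small_cfg <- function(...) {
  default_config(cohort = list(n = 1000L), ...)
}

# expectation-like stub for testing the cost-effectiveness arithmetic on
# chosen summary values
stub_arm <- function(cost, qaly) {
  structure(list(arm = "stub", cost = cost, qaly = qaly, ly = NA_real_),
            class = "thyrocea_expectation")
}
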