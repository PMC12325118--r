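Package: thyrocea
Title: Cost-Effectiveness Microsimulation of Digital Monitoring for Hyperthyroidism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic Markov microsimulation of the clinical course of
    hyperthyroidism under usual care and under wearable-based digital
    thyroid-function monitoring, from the perspective of the Korean health care
    system. Provides a patient-level discrete-time simulation engine with a
    matching deterministic cohort-expectation oracle, a parametric
    (Gompertz-Makeham) life-table generator, calibration of structural effect
    parameters to published state-occupancy shares, cost-effectiveness
    statistics (QALYs, ICER, net monetary benefit), one-way deterministic
    sensitivity analysis with tornado ranking, subscription-fee threshold
    analysis, and probabilistic sensitivity analysis with beta/gamma parameter
    sampling and cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
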