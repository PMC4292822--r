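Package: hrhsim
Title: Needs-Based Health-Workforce Supply and Requirements Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time, deterministic simulation engine for needs-based
    human-resources-for-health (HRH) planning. Projects the regional headcount
    of licensed providers with a single-year-of-age stock-and-flow model fed by
    a lagged training pipeline, converts headcounts to full-time-equivalent
    (FTE) service capacity through participation and activity rates, computes
    FTE requirements from population size, condition prevalence and planned
    levels of service, and compares policy scenarios (training seats, public
    sector retention, productivity growth) against the projected
    supply-requirement gap. Ships a calibrated baseline for pharmacists in
    Jamaica's South East Regional Health Authority together with a seeded
    synthetic-case generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
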