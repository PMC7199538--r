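Package: bedalloc
Title: Data-Driven Two-Class Allocation of Inpatient Beds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "bedalloc@example.org",
           role = c("aut", "cre"))
Description: Data-driven allocation of scarce inpatient beds between urgent
    and regular elective patients. Implements a single-period two-class
    newsvendor model with exact, sample-average-approximation and
    feature-based kernel-optimization solvers; a multiperiod admission model
    with random bed release comparing kernel-optimization against fixed-ratio
    allocation; and a multiperiod revenue-plus-equity model with day-of-week
    reservation quotas, waiting costs and extra-bed penalties, including
    sensitivity sweeps over the control and cost parameters. Ships synthetic
    generators for demand series, bed-release processes and full hospital
    traces so the pipelines can be exercised without access to restricted
    hospital records.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
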