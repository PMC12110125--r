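Package: evenwork
Title: Entropy-Based Analysis of Workload Distribution Among Personnel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing how evenly workload is distributed among an
    institution's personnel, developed for health-services workforce
    analytics. Normative workloads are modelled in time credits from
    per-category effective-time and daily-loss fractions, actual workloads
    are accumulated from a service log against a time-and-motion service
    catalog, and evenness is quantified with base-2 Shannon entropy of
    normalized workload, free-time-reserve and excess-work shares, reported
    relative to the group maximum log2(n). A scenario engine flags
    managerial decision cases (hire, expand services, relieve, rebalance)
    from configurable thresholds, a bundled dental-clinic dataset
    illustrates the full pipeline, and a seeded generator simulates clinics
    with controllable workload imbalance for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
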