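Package: teleroi
Title: Return-on-Investment and Breakeven Analysis for Telehealth Care Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A configuration-driven pipeline for deterministic economic
    evaluation of outpatient care-delivery models (patient travel,
    hub-and-spoke telehealth, and rural-employed virtual health
    practitioners). Builds per-clinic staffing costs from hourly rates,
    on-costs and hours; discounts multi-year cost streams; computes
    activity-based-funding income with failure-to-attend adjustment;
    assembles net benefit, return on investment and breakeven attendance
    per site; and runs one-way sensitivity sweeps over attendance and
    travel-subsidy uptake. Ships a transcribed orthopedic fracture-clinic
    case study and a seeded synthetic activity generator so every stage
    is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
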