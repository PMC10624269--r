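Package: palneed
Title: Palliative Care Need, Symptom Burden, Opioid Access, and Workforce Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A deterministic accounting pipeline for needs-based palliative
    care planning at country level. Converts cause-specific mortality and
    prevalence envelopes, together with condition-by-symptom prevalence and
    duration coefficients, into counts of decedents and non-decedents in need
    of palliative care; computes lower ("at-least") and upper ("at-most")
    bounds on symptom-days of serious health-related suffering; converts
    distributed opioid quantities to oral morphine equivalents (DOME) and
    compares them with a modelled opioid requirement; and translates patients
    in need into encounter-days at five care levels and full-time-equivalent
    staffing requirements for ten staff categories. Includes a seeded
    synthetic-scenario generator so the full pipeline can be exercised and
    validated without external data downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    readr,
    rlang,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
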