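Package: udtrisk
Title: Risk-Stratified Random Urine Drug Testing for Chronic Opioid Therapy
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for risk-stratified, probabilistically scheduled urine drug
    testing (UDT) of patients on chronic opioid analgesic therapy (COAT).
    Converts opioid prescriptions to daily morphine milligram equivalents
    (MME) with a configurable equianalgesic table, assigns an ordered
    four-level risk category from the daily dose and clinical risk factors
    (age under 45, concomitant benzodiazepine use, history of inconsistent
    toxicology), issues seeded random test recommendations at category-specific
    frequencies, classifies toxicology panels as consistent or inconsistent
    with the prescribed opioids (with a tetrahydrocannabinol exclusion rule and
    reason codes), simulates synthetic cohorts with within-patient correlation,
    and evaluates testing programmes with category summaries, crude odds
    ratios, and cluster-robust logistic regression fitted by generalized
    estimating equations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
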