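Package: regcost
Title: Matched-Cohort Cost-of-Illness Analysis from Health Register Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A register-based pipeline for prevalence-based cost-of-illness
    analysis of mental disorders with a matched case-cohort design. Builds
    censored follow-up windows from civil-registration data, identifies cases
    from psychiatric contact records by ICD-10 code sets, attaches ten
    incidence-density matched controls per case (same sex, birthdate within
    two calendar months, index-disorder free at the index date), assembles
    per-person annual cost panels in inflation-adjusted 2017 Euro (psychiatric
    and somatic hospital DRG tariffs, subsidised prescriptions, primary care,
    personal income and nine public transfer components), and estimates
    nationwide, per-case and per-capita absolute and excess costs stratified
    by sex, age band and years since diagnosis. A synthetic register generator
    with known ground truth makes every stage testable without access to the
    confidential source registers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    lubridate,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
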