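Package: dqipr
Title: Explicit Medication Assessment Criteria for Prescribing Quality and Safety Screening
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An executable implementation of an explicit medication assessment
    instrument for UK-style primary care records. Encodes 176 prescribing
    quality and safety criteria as declarative rules evaluated over
    longitudinal patient records (conditions, prescriptions, laboratory and
    blood-pressure observations), including drug exposure-episode
    construction with a refill grace gap, CHADS2 stroke-risk scoring, CKD
    staging, and dose-equivalence arithmetic. Also implements the
    RAND/UCLA appropriateness method classifier (with the
    'necessary to avoid' extension) and the Delphi priority-tier classifier
    used to derive and prioritise the criteria, and a synthetic cohort
    generator that plants positive and single-clause-mutated negative cases
    for every criterion so the whole instrument is testable without access
    to real patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lubridate,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
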