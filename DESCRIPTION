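Package: osteocca
Title: Markov Cohort Cost-Consequence Model for Continuous Denosumab
    Therapy in Osteoporosis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A deterministic Markov cohort model comparing continuous
    denosumab therapy against discontinuation in osteoporosis patients
    whose bone-mineral-density T-score has recovered above the
    reimbursement threshold. Tracks T-score health states and fracture
    sub-states over 6-month cycles, applies life-table background
    mortality with standardized mortality ratios after fracture, and
    accrues drug, administration, fracture-treatment and productivity
    costs, discounted and undiscounted. Includes a cost-consequence
    summary layout, one-way sensitivity analysis, an individual-level
    microsimulation used as an independent validation oracle, and
    generators for synthetic life tables and productivity profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
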