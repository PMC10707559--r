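Package: lipidscore
Title: Lipid Athlete Score and Dyslipidemia Screening for Athlete Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for cardiovascular lipid screening in elite-athlete
    cohorts: cardiovascular risk-factor and dyslipidemia classification
    from standard lipid panels, empirical ROC analysis with
    maximum-efficiency cut-point selection for atherogenic indices such
    as the LDL/HDL ratio, a major/minor-criteria "lipid athlete score"
    with a four-tier risk classification, descriptive group-comparison
    tables and univariate 2x2 odds ratios, and a seedable synthetic
    cohort generator calibrated to published Olympic-athlete summary
    statistics so the full pipeline is testable without individual-level
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
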