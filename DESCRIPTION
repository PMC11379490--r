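Package: cvdprs
Title: Integrating a Cardiovascular Polygenic Risk Score with Clinical
    10-Year Risk Scores in Nested Case-Control Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate whether adding a cardiovascular disease
    polygenic risk score (CVD-PRS) to clinical 10-year risk equations
    (QRISK2 passthrough/surrogate, ASCVD pooled cohort equations, SCORE2)
    through an integrated risk tool identifies more future cases as high
    risk. Provides pre-imputation genotype quality control (call rate,
    minor allele frequency, Hardy-Weinberg exact test), polygenic score
    alignment and scoring with ancestry standardisation, log-odds
    integration of the standardised score with clinical risk, hierarchical
    case selection with propensity-score matching and balance diagnostics,
    paired sensitivity comparison with Wald inference, reclassification
    and percentile-enrichment statistics, a parameterised preventable-events
    model, and a synthetic-cohort generator that emulates the statistical
    structure of an NHS Health Check population so the full pipeline is
    testable without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
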