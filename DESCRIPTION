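Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for pharmacovigilance signal detection on FAERS-style
    spontaneous-report databases: reads quarterly ASCII report tables,
    deduplicates case versions, maps MedDRA preferred terms to system organ
    classes, builds drug-event 2x2 contingency tables, and computes four
    disproportionality statistics (reporting odds ratio, proportional
    reporting ratio with chi-square, the Bayesian confidence propagation
    neural network information component, and the empirical Bayes geometric
    mean) with interval estimates and a four-algorithm consensus signal rule.
    Includes descriptive report profiling, cumulative information-component
    time scans, a synthetic report-database generator with planted
    association strengths for end-to-end validation, and a numeric inversion
    oracle that reconstructs contingency tables from published statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table (>= 1.14),
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
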