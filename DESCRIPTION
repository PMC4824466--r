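Package: hospbench
Title: Hospital Profiling with Case-Mix-Adjusted Standardized Risks and
    Benchmark Decision Rules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling hospital performance on a binary patient
    outcome. Fits a fixed-effects multiple logistic regression for case-mix
    adjustment, computes directly standardized hospital risks with
    delta-method standard errors, classifies hospitals against a benchmark
    defined as (1 + delta) times the observed population risk at a chosen
    one-sided confidence level k, and evaluates the operating
    characteristics (sensitivity, specificity, predictive values) of the
    decision rule by parametric bootstrap. Includes a synthetic stroke-
    registry generator calibrated to published national quality-register
    summaries, and a theoretical ROC planner for choosing delta and k.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
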