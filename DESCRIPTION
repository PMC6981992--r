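Package: unsafebn
Title: Bayesian Network Analysis of Unsafe-Behavior Chains in Construction Accidents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how coded unsafe behaviors transmit probability
    to occupational accidents. Reads behavior catalogs and accident-case files,
    extracts time-ordered chains of unsafe behaviors, learns a tree-augmented
    naive Bayes network linking binary behavior indicators to accident types
    (fall, collapse, struck-by, lifting), and provides exact forward reasoning
    (accident-type posteriors under accumulating evidence), attribute-strength
    quantification, and an iterative backward-diagnosis procedure that
    identifies critical groups of co-occurring unsafe behaviors. Includes a
    synthetic case generator with known ground truth for validating structure
    learning, parameter recovery and diagnosis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
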