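Package: trendseg
Title: Segmented Regression Analysis of Expression Dynamics over Ordered
    Conditions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Characterizes gene expression dynamics in time-course (or any
    ordered-condition) profiling experiments by fitting per-gene segmented
    (piecewise-linear) regression models with an unknown number of
    breakpoints. The breakpoint count is chosen by BIC, a minimum-samples-
    per-segment guard protects against overfitting, fits are gated by
    adjusted R-squared, and each segment is classified as rising, falling
    or flat from its slope t-statistic. Transcriptome-level summaries
    include the breakpoint distribution over time points, an encoded
    trend matrix suitable for clustering, and pattern extraction. A
    simulation harness generates null (shuffled/trendless) and true-trend
    datasets with known breakpoints for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
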