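Package: zcombine
Title: Combined Tests of Dependent Partial Tests via z-Scores in Large-Scale
    Expression Screens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tests complex per-gene hypotheses built from dependent partial
    tests that share a common control arm, as in multi-compound expression
    experiments. Implements the Stouffer z-score combined test whose null
    variance is estimated from the genes themselves (sample covariance of
    partial z-scores, with an optional zero-assumption null-gene selection
    step and truncation-consistent correction), permutation-calibrated
    Tippett minimum-p and Fisher omnibus tests, Dunnett's many-to-one test,
    Storey q-values, and a simulation harness that evaluates ROC curves,
    DEG rank statistics, and realized false discovery proportions on
    synthetic multi-arm experiments with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
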