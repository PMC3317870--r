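Package: spanel
Title: Fixed-Effects Spatial Panel Models for Ecological Health Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Estimation and diagnosis of fixed-effects spatial panel
    regressions for areal health outcomes such as municipal infant
    mortality rates.  Provides binary contiguity weight matrices on
    regular lattices and in the GAL interchange format, spatially lagged
    (neighbour-average) covariates, the within (demeaning) transformation
    with recovery of the constant and the regional effects, pooled and
    fixed-effects least squares, maximum-likelihood spatial-error and
    spatial-lag panel estimators with eigenvalue-based log-determinants
    and an iterative two-stage procedure for the error model,
    Lagrange-multiplier spatial-dependence diagnostics with robust
    variants, a Breusch-Pagan residual check, a first-difference
    specification for temporal trends, and a calibrated synthetic
    municipality-panel generator for method validation.
License: MIT + file LICENSE
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    stats,
    utils,
    withr
Suggests:
    lmtest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
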