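Package: dsdpower
Title: Criticality Assessment of Process Parameters via Retrospective Power Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for criticality assessment of process parameters in
    biopharmaceutical process characterization studies. Builds definitive
    screening designs, derives intermediate-stage thresholds from
    drug-substance specifications and specific clearance factors, computes
    a priori design-of-experiments power averaged over randomized
    critical-effect-weight combinations (noncentral F), fits stepwise
    multiple linear regression models to DoE responses, estimates
    retrospective per-parameter power with a residual-permutation test,
    scans the effect of tightening normal operating ranges, and orchestrates
    the full criticality-assessment workflow with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
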