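Package: phageburst
Title: Single-Cell Phage Burst Size Distributions and Noise Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing single-cell bacteriophage burst sizes
    measured by limiting-dilution plaque assays. Implements a saturating
    (sigmoidal) model of mean burst size as a function of lysis time, its
    nonlinear least-squares fit, and a first-order noise-propagation
    decomposition of the burst-size coefficient of variation into
    contributions from cell-to-cell variability in cellular phage-production
    capacity, half-maximal lysis time, and intracellular growth rate.
    Includes Poisson occupancy calculations for 96-well limiting-dilution
    designs, per-lysis-time distribution summaries (CV, CV-squared, moment
    skewness, outlier trimming, bootstrap confidence intervals), two tests
    for equality of coefficients of variation across groups, and a
    synthetic-assay generator that emulates the full plate-based experiment
    so each analysis stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
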