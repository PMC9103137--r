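Package: mgrselect
Title: Biomarker Interaction Selection and Disease Detection with the
    Multivariate Gain Ratio
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects interactions (subsets) of discrete biomarkers that
    jointly determine a binary disease status. Implements the I-score and
    Multivariate Gain Ratio influence measures over partition tables, a
    backward-dropping greedy subset search with principled initial-size and
    repetition calculators, triple-based screening for high-dimensional
    expression data, return-set overlap filtering and forward adding, and a
    boosted ensemble of ridge-regression sub-classifiers with interaction
    product terms, evaluated by stratified cross-validation. Includes
    synthetic generators and bias-characterization experiments for the two
    measures, plus the standard expression-array preprocessing recipe
    (clamping, variability filtering, log10, two-means discretization).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
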