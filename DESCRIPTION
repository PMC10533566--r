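Package: salisense
Title: Chemometric Analysis of Paper-Based Colorimetric Saliva Sensor Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 12-spot paper-based colorimetric sensor
    arrays used to screen saliva for diabetes-associated metabolic changes.
    Extracts per-spot RGB difference features from before/after scanner
    images, scores experimental conditions with the discrimination ability
    function (inter- over intra-group variance), classifies samples by the
    Euclidean norm of the 36-element response vector and by PCA-LDA with
    cross-validation, and correlates receptor responses with fasting blood
    glucose. Includes a synthetic cohort and response generator calibrated
    to published demographic and response statistics so every stage can be
    exercised without access to the original clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    png,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
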