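Package: orscreen
Title: Screening Analysis for Matching Odorants to Olfactory Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A three-stage analysis pipeline for high-throughput
    dual-luciferase screens that match odorants to olfactory receptors:
    primary-screen plate standardization against on-plate Olfr544 standard
    wells with baseline subtraction and top-fraction hit selection, a
    one-way ANOVA concentration-effect filter on secondary-screen
    triplicates, and sigmoidal dose-response fitting with a composite
    three-criterion agonist call (top/bottom confidence-interval
    separation, log EC50 precision, and an extra sum-of-squares F test
    against the empty-vector control). Includes readers and writers for
    the five tab-separated screening data schemas, ROC validation of each
    stage against the next, and a ground-truthed synthetic screen
    generator emitting the same schemas.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    stats,
    utils,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
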