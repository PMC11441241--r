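Package: lipidflux
Title: Lipidome Preprocessing, Enrichment and Remodeling Analysis for
    Condition-Contrast Shotgun Lipidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline that turns raw lipid-identification exports
    (one row per identified lipid ion) into condition-contrast results for
    two-batch, two-condition designs: LIPID MAPS shorthand parsing at the
    molecular-species and sum-composition levels, quality and blank
    filtering, internal-standard and median normalization, presence
    filtering, parametric empirical-Bayes batch adjustment, principal
    component analysis with squared-loading contributions, Fisher's exact
    test for lipid-class enrichment among dimension-spanning species,
    exclusive-species detection, double-bond and fatty-acyl profiling, and
    multiple Welch t-tests with Holm-Sidak step-down correction. Includes a
    synthetic-data generator with planted ground truth so every stage is
    verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    sva,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
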