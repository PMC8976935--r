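Package: glaucodx
Title: Diagnostic Performance of OCT and Visual-Field Summary Metrics for Early Glaucoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A criterion engine and evaluation pipeline for glaucoma
    diagnostic summary metrics. Represents diagnostic rules over
    color-coded optical coherence tomography (OCT) sector metrics and
    Humphrey visual-field (VF) indices as composable boolean predicate
    trees, including a structure-structure hemifield agreement metric,
    paired-sector OCT agreement, quadrant-plus-GHT structure-function
    agreement, and Brusini GSS2 staging. Implements an automated
    topographic structure-function reference standard that labels eyes
    as likely glaucoma from counts of abnormal-structure/
    abnormal-function visual-field locations replicated across two
    baselines, and computes sensitivity, specificity and accuracy with
    percentile bootstrap confidence intervals. Ships a synthetic cohort
    generator with hemifield-localised, cross-measure-correlated
    abnormalities so the whole pipeline is testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
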