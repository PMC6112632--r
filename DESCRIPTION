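Package: cvssrasch
Title: Rasch, Factor and Discriminant Validation of Polytomous Symptom Scales
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Psychometric validation pipeline for short polytomous
    patient-reported outcome scales, built around the 17-item
    computer-vision symptom scale (CVSS17). Fits the partial credit
    Rasch model by joint maximum likelihood; derives score-to-measure
    tables, person separation, targeting and residual-PCA
    dimensionality; counts statistically distinct levels of
    performance by Wright's sample-independent method and derives
    raw-score severity cutoffs; confirms factor structure via
    principal-component extraction with varimax rotation, KMO and
    Bartlett checks; classifies persons into severity levels from
    factor scores by linear discriminant analysis; screens items for
    differential item functioning by Mantel-Haenszel and anchored
    logit-difference methods; grades subscale quality on an A/B/C
    scheme; and generates synthetic response data with the assumed
    bifactor structure for end-to-end testing and parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
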