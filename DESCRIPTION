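Package: sgecurate
Title: Clinical Variant Curation with Paired Saturation Genome Editing
    Functional Evidence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Point-based ACMG/AMP classification of germline variants and
    integration of functional evidence from paired saturation genome editing
    (SGE) assays. Parses ACMG/AMP evidence-code tokens with strength
    modifiers, aggregates signed evidence points into the five-tier
    classification, assigns PS3/BS3 when two SGE datasets agree, combines
    likelihood ratios with a prior probability into a Bayesian posterior and
    IARC class, and scores the agreement of each functional dataset against
    a clinical classification (major error, minor error, concordance) with a
    Bhapkar marginal-homogeneity comparison. Includes a synthetic-cohort
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
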