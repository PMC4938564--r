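Package: toxprs
Title: Polygenic Breast-Cancer Risk Scores and Chemotherapy Toxicity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds weighted and non-weighted polygenic risk scores from a
    94-variant breast-cancer susceptibility catalog and tests their
    association with dichotomized chemotherapy toxicity phenotypes
    (neutropenia grade >=3, taxane-related sensory neuropathy grade >=2).
    Includes genotype quality control with an exact Hardy-Weinberg test,
    principal-component covariates, a ranked-gene Fisher
    overrepresentation procedure against GMT gene sets, analytic and
    simulated case-control power calculations, a proportional-hazards
    linkage of the score to relapse-free survival, and a synthetic-cohort
    generator (Hardy-Weinberg dosages with imputation noise, toxicity
    grades, covariates and survival times) so the full pipeline is
    testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml,
    fgsea,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
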