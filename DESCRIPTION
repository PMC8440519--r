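Package: concord
Title: Common and Unique Brain Changes Between Patient Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies disorder-common and disorder-unique brain
    functional and structural abnormalities between two patient groups
    (schizophrenia, autism spectrum disorder) and healthy controls.
    Provides mask-based normalization quality control, three-step
    covariate and dataset-effect harmonization, functional network
    connectivity (FNC) and ROI-based functional connectivity
    construction, ANOVA-gated sign-based change categorization with
    quantification of weaker changes in one disorder, permutation-null
    and Fisher's-method meta-analytic validation, symptom and medication
    association testing, and categorization-driven cross-dataset linear
    SVM classification. A synthetic multi-dataset cohort generator with
    planted effects supplies ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    signal,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
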