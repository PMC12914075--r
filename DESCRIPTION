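Package: picpmed
Title: Proteomic Mediation Analysis of Antifibrotic Treatment Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline linking randomized treatment effects on a
    serum fibrosis biomarker (PICP, procollagen type I C-terminal propeptide)
    to a longitudinal Olink NPX protein panel. Provides a synthetic trial
    generator with closed-form causal ground truth, consensus feature
    selection across four regression learners with permutation importance,
    multi-mediator causal mediation with a signature score and
    leave-one-out mediated-proportion loss, random-slope trajectory models
    with slope-on-slope regression, quartile trend and interaction
    statistics, and hypergeometric over-representation analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    lme4,
    glmnet,
    ranger,
    xgboost,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
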