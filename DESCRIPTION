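Package: evonnet
Title: Evolutionary Neural-Network Classifiers for Treatment-Uptake Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains sparse product-unit, sigmoid-unit and radial-basis-function
    neural network classifiers by an evolutionary algorithm that searches both
    architecture and weights, targeting imbalanced binary clinical outcomes such
    as hepatitis C treatment uptake in HIV/HCV co-infected cohorts. Includes a
    synthetic cohort generator emulating the HERACLES variable schema with a
    configurable planted logistic outcome model, basis-specific input scaling,
    holdout evaluation with correct classification rate, minimum sensitivity,
    ROC and precision-recall analysis, a repeated-runs protocol with
    ANOVA/Levene/Tukey method comparison, and variable-ablation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    nortest,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
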