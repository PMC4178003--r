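Package: sepsipanel
Title: Multi-Biomarker Panel Selection and Severity Scoring for Pediatric Sepsis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating multi-biomarker severity
    classifiers on longitudinal pediatric intensive-care cohorts. Implements
    exhaustive canonical-correlation best-subset selection of biomarker
    panels, a class-weighted 1-norm (sparse) linear support vector machine
    solved as a linear program, bagged ensemble evaluation with repeated
    random splits reporting sensitivity, specificity, and predictive values,
    out-of-bag permutation importance for random forests, the published
    three-biomarker (angiopoietin-2, angiopoietin-1, bicarbonate) severity
    score with longitudinal trajectories, and a seeded synthetic cohort
    generator that emulates the statistical structure of the study data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    randomForest,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
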