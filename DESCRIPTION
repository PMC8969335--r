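Package: landmark
Title: Oblique and Non-Linear Decision Tree Ensembles for Biomarker Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ensemble classifier for sparse presence-absence marker-gene
    (amplicon sequence variant) tables in which every tree node learns a
    multivariate splitter -- regularized logistic regression, linear support
    vector machine, stochastic-gradient linear models, ridge classification,
    or a two-branch neural network -- selected by information gain, optionally
    preceded by a random linear oracle hyperplane. Includes a synthetic
    presence-absence perturbation generator with known ground truth,
    evaluation metrics (a confusion-matrix balanced accuracy variant,
    feature-recovery Matthews correlation, Cohen's kappa), ensemble-geometry
    diagnostics (terminal-leaf proximity, sqrt(1-p) dissimilarity, principal
    coordinates, kappa-error diagrams), kernel Shapley importances, and a
    recursive-feature-elimination biomarker-selection workflow with
    half-split consistency and multi-model benchmarking harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    ranger,
    jsonlite
Suggests:
    biomformat,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
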