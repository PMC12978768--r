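Package: ecga4d
Title: Electron-Conformational 4D-QSAR with Genetic-Algorithm Descriptor
    Selection and Stacked Ensemble Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for four-dimensional quantitative structure-activity
    relationship (4D-QSAR) modelling over conformer ensembles. Builds
    electron-conformational matrices of contiguity (ECMC) from per-conformer
    geometries and electronic properties, mines tolerance-bounded
    pharmacophore submatrices (ECSA) that separate high- from low-activity
    compounds, fits a Boltzmann-weighted activity model with an
    antipharmacophore shielding term by nonlinear least squares, selects
    descriptor subsets by a genetic algorithm with leave-one-out PRESS
    fitness, and trains a gradient-boosting / random-forest stacked hybrid
    regressor with recursive feature elimination. Includes seeded synthetic
    data generators for every input the pipeline consumes and the standard
    QSAR validation statistics (PRESS, q2, external q2 variants, k-fold Q2).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    randomForest,
    rpart,
    stats,
    utils
Suggests:
    ChemmineR,
    nnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
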