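Package: lanbind
Title: Machine Learning Prediction of Lanthanide-Ligand Binding Affinities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A QSPR (quantitative structure-property relationship) toolkit for
    predicting stability constants (logK1) of 1:1 lanthanide-ligand complexes.
    Ligand structures (SDF/MOL/SMILES) are featurized into a fixed 102-dimensional
    vector combining 83 molecular descriptors with properties of the metal cation,
    the solvent medium and the experimental conditions (temperature, ionic
    strength). The package provides six feature scalers, a zoo of ten regressors
    (random forest, k-nearest neighbours, support vector machines, kernel ridge
    regression with four kernels, a multilayer perceptron and AdaBoost.R2),
    impurity and permutation feature importance, a bounding-box applicability
    domain, streaming compound-library screening under standard conditions, and
    matched-condition cation-pair selectivity metrics. A seeded synthetic-data
    generator emulating the statistical shape of curated stability-constant
    compilations makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils,
    methods,
    rpart,
    randomForest,
    e1071,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
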