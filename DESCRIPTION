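Package: cytoweight
Title: Metaheuristic Feature Weighting for Cervical Cytology Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for weighted deep-feature classification of single-cell
    cervical cytology (Pap smear) images. Provides seeded synthetic cell-image
    and feature-table generators for the seven-class Herlev layout, scenario
    masking (whole cell, nucleus-excluded, nucleus-only), random geometric
    augmentation with class balancing, a seven-features-per-extractor deep
    feature contract with deterministic mock extractors, PCA loading-magnitude
    feature selection, Ant Lion Optimization (ALO) and Particle Swarm
    Optimization (PSO) feature weighting driven by cross-validated classifier
    accuracy, polynomial-kernel SVM and random-forest classification under
    stratified k-fold cross-validation, and a confusion-matrix metric suite.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    e1071,
    randomForest,
    withr,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Collate:
    'cytoweight-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'herlev.R'
    'synthetic-images.R'
    'synthetic-features.R'
    'imageops.R'
    'features.R'
    'selection.R'
    'classify.R'
    'weighting.R'
    'optimizers.R'
    'metrics.R'
    'pipeline.R'
    'io.R'
RoxygenNote: 7.3.3
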