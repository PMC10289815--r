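Package: OlivePhen
Title: RGB Image Phenotyping of Olive Fruit Quality Traits with
    Backpropagation Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts olive fruit oil and total phenol concentrations from
    RGB colorimetric indexes extracted from segmented fruit images. Provides
    a synthetic benchmark generator emulating seasonal cultivar trajectories,
    white-balance and CIELAB-threshold segmentation utilities, a registry of
    35 RGB colorimetric indexes, principal component analysis with a
    cumulative-variance cutoff, cardinality-constrained sparse PCA with a
    genetic algorithm selecting the number of nonzero loadings per component,
    single-hidden-layer regression networks trained by resilient
    backpropagation (Rprop+), and repeated hold-out evaluation with a
    composite general performance indicator that ranks model variants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    S4Vectors,
    SummarizedExperiment,
    EBImage,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
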