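Package: qsrr2d
Title: Retention-Time and Retention-Index Prediction for Comprehensive
    Two-Dimensional Gas Chromatography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative structure-retention relationship (QSRR) modelling
    for comprehensive two-dimensional gas chromatography (GCxGC). Computes
    first-dimension linear retention indices from n-alkane series and
    second-dimension retention indices anchored to a polyethylene-glycol
    reference line; engineers descriptor matrices (weight normalisation,
    linearising transformations, unit-variance autoscaling); splits compound
    sets by systematic sampling along principal-component scores; fits
    NIPALS partial least squares models with cross-validated component
    selection, variable importance on projection (VIP), jackknife
    coefficient uncertainties, descriptor-pruning ladders and per-group
    local models; predicts retention by a federation-of-local-models
    nearest-neighbour regression over a knowledge base; and evaluates,
    benchmarks and screens candidate structures with 95-percentile error
    windows and a PCA-based applicability domain. Includes a synthetic
    compound-set generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ChemmineR,
    mixOmics,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'containers.R'
    'descriptors.R'
    'splitting.R'
    'evaluation.R'
    'federation.R'
    'indexing.R'
    'io.R'
    'pls.R'
    'pipeline.R'
    'qsrr2d-package.R'
    'synthetic.R'
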