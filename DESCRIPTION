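Package: enmecotype
Title: Ecological Niche Modelling Workflow for Delineating Livestock Ecotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end presence-background ecological niche modelling
    workflow for proposing candidate livestock ecotypes from village-level
    occurrence records and gridded environmental layers. Provides plain-text
    raster stack handling, occurrence expansion from village coordinates,
    correlation/PCA/iterative variable screening, a from-scratch L1-regularized
    maximum-entropy model fitter with feature-class and beta-multiplier
    selection by small-sample-corrected AIC, model evaluation (AUC, jackknife,
    percent contribution, permutation importance, response curves), pairwise
    niche similarity (Pearson map correlation, Hellinger overlap I, Schoener's
    D), and agglomerative clustering of populations into ecotypes with linkage
    selection by agglomerative coefficient. A synthetic correlated landscape
    generator with planted ecotype suitability surfaces makes the whole
    pipeline runnable and testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff,
    ape,
    cluster,
    mclust,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
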