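Package: brainpls
Title: Partial Least Squares Correlation of Risk-Factor Panels and Brain
    Morphology with Spatially Constrained Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Latent-dimension analysis linking a multivariate cardiometabolic
    risk-factor panel to regional brain morphometry. Implements partial least
    squares (PLS) correlation via singular value decomposition of the
    cross-block correlation matrix, with permutation significance testing,
    bootstrap stability (bootstrap ratios and loading confidence intervals),
    subject scores, and cross-validation; single-mediator bootstrap mediation
    of cognition by brain structure; and spatial contextualization of parcel
    effect maps against cell-type expression (ensemble gene-category
    enrichment) and connectome topology (degree centrality, neighborhood
    abnormality, connectivity gradients) using spin, variogram-matched,
    spatial-lag, and degree-preserving rewiring null models. A synthetic
    cohort generator with planted latent coupling, confound contamination,
    missingness, mediation structure, spatially autocorrelated maps, modular
    connectomes, and category-structured expression makes the full pipeline
    testable without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
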