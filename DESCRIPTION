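Package: nichemax
Title: Penalized Maximum-Entropy Habitat Suitability Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A self-contained pipeline for presence-only species
    distribution modelling: grid-based spatial thinning of occurrence
    records, ESRI ASCII raster handling, Pearson collinearity screening of
    bioclimatic layers, an L1-penalized maximum-entropy (Gibbs) density
    estimator with linear, quadratic, hinge, product and threshold
    features, AICc model selection over a regularization-multiplier by
    feature-class grid, discrimination and variable-importance
    diagnostics, four-level suitability classification with spherical
    area accounting, climate-scenario comparison and range-centroid
    shift analysis. Includes a virtual-species simulator (Gaussian
    random field landscapes, Gaussian niche responses) so every stage
    is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
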