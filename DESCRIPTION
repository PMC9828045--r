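Package: morphomod
Title: Evolutionary Modularity and Integration of 3D Landmark Shape Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for testing a priori hypotheses of evolutionary modularity
    and integration in three-dimensional landmark configurations across a
    time-calibrated phylogeny. Provides Generalized Procrustes superimposition
    with object-symmetry decomposition, phylogenetic allometry checks,
    covariance-ratio (CR) modularity tests with permutation nulls and effect
    sizes, maximum-likelihood comparison of modularity hypotheses via shared
    or separate within/between-module correlation coefficients compared by
    AICc, penalized-likelihood fitting of multivariate Brownian motion,
    Ornstein-Uhlenbeck and early-burst trait models with GIC model selection
    and phylogenetic half-lives, multivariate rate comparisons, per-module
    disparity, and a synthetic-data generator producing modular landmark
    datasets evolved on ultrametric trees for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
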