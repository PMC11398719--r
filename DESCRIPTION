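Package: connlife
Title: Structural Connectome Efficiency and Cognition Across the Lifespan
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for relating structural brain connectivity to
    cognitive ability across the adult lifespan. Provides quality control and
    consistency thresholding of subject-level streamline-probability
    connectomes, weighted graph measures (nodal efficiency, local efficiency,
    clustering, characteristic path length, small-worldness), behavioral
    partial least squares with permutation, bootstrap-ratio and split-half
    reproducibility inference, rolling-window age correlations with BCa
    bootstrap confidence intervals, and multilinear models of whole-brain
    network structure. Includes a synthetic cohort generator with planted
    brain-behavior latent structure so every stage is testable by recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, StatisticalMethod
RoxygenNote: 7.3.3
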