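Package: RidgePcor
Title: Gene-Specific Ridge Partial Correlation Networks with Interaction-Network Priors
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates gene co-expression networks through gene-specific ridge
    partial correlations: the regression used to residualize each gene pair is
    penalized per controlling gene by the inverse of a personalized PageRank
    score computed on a protein-protein interaction prior graph, so that genes
    topologically close to the pair in the prior are preferentially used to
    remove indirect correlation. Includes bootstrap significance and
    case/control permutation tests for network edges with Benjamini-Hochberg
    control, consensus modularity clustering across a grid of regularization
    parameters with a Poisson co-clustering test, a Monte-Carlo test for
    regional clustering of GWAS loci, and a synthetic-data generator with
    known Gaussian-graphical-model ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    MASS,
    SummarizedExperiment,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: NetworkInference, GraphAndNetwork, GeneExpression, Network
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
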