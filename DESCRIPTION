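Package: mirdirect
Title: Direct miRNA-mRNA Association Networks from Matched Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers direct microRNA-mRNA association networks from matched
    expression matrices. Combines three direct-correlation estimators
    (Schafer-Strimmer shrinkage partial correlation, sparse partial
    correlation by joint L1-penalized regression, and mutual-information-based
    network deconvolution) with bootstrap resampling and inverse-rank-product
    ensemble aggregation, producing ranked bipartite edge lists that can be
    evaluated against validated miRNA-target databases and exported for
    Cytoscape. Includes a synthetic benchmark generator based on sparse
    bipartite Gaussian graphical models with transitive indirect correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
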