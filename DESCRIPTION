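Package: pitcherwebs
Title: Trophic Diversity and Path Analysis of Pitcher-Plant Food Webs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dendrogram-based trophic diversity (TD) of the
    Sarracenia purpurea inquiline food web and for maximum-likelihood path
    analysis of decomposition. Computes TD as the total branch length of a
    hierarchical clustering of species' trophic interaction profiles, with
    distance/linkage selection by cophenetic correlation; enumerates species
    combinations and emits TD-stratified experimental designs; fits
    observed-variable path models (recursive structural equation models) to
    sample covariance matrices by maximum likelihood with chi-square, CFI,
    BIC and R-squared reporting and delta-BIC model ranking; and simulates
    synthetic decomposition experiments from a linear structural model for
    testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
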