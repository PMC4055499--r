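Package: asdconnectome
Title: Graph-Theoretic and Machine-Learning Analysis of Multiparametric
    Brain MRI Features in Autism Spectrum Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Small-world network analysis of functional and structural
    (cortical thickness and volumetry) brain connectivity, quantitative
    resting-state feature extraction (seed-based connectivity summaries,
    homotopic connectivity, fractional amplitude of low-frequency
    fluctuations), PCA/mRMR feature integration, randomized-tree
    classification and instance-based phenotype regression for two-group
    (autism spectrum disorder versus typically developing) cohorts.
    Includes a synthetic-cohort generator with configurable planted
    group effects so that every stage of the pipeline can be exercised
    and calibrated without access to raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
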