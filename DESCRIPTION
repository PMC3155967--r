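Package: retscreen
Title: Factorial ANOVA Screening and In Situ Validation of Retinal Gene
    Expression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying chromatin-remodeller-regulated retinal
    genes from 2x2x2 factorial expression experiments (mutation x tissue x
    developmental stage) and validating them against qualitative in situ
    hybridization (ISH) observations. Implements per-gene saturated
    three-way ANOVA fits with parsimonious model-class assignment,
    contrast inference with Benjamini-Hochberg false-discovery-rate and
    two-fold-change filters, functional-group classification,
    microarray/ISH concordance scoring with a proportion z test against a
    theoretical true discovery rate, and hierarchical clustering of binary
    gene-by-retinal-domain matrices with multiscale-bootstrap
    approximately-unbiased (AU) clade support. A synthetic-data module
    generates every input the pipeline consumes so all stages are testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    ape,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GeneExpression, Microarray, Clustering, DifferentialExpression
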