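Package: fibronet
Title: Systems Genetics of Fibrosis-Associated Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for identifying disease-associated gene
    co-expression networks and their trans-acting genetic regulators.
    Implements robust (biweight midcorrelation) co-expression module
    inference with topological overlap and eigengene merging, pre-ranked
    gene set enrichment analysis against quantitative traits, cross-species
    module conservation testing over one-to-one ortholog backgrounds,
    an empirical differential co-expression (dispersion) permutation test,
    and sparse Bayesian variable selection for mapping a module's joint
    expression to genotypes, with Bayes-factor summaries and median-BF
    locus calling. A synthetic-data generator with planted ground truth
    (recombinant-inbred-style genotype panels, case/control cohorts and
    fibrosis-like phenotypes) supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
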