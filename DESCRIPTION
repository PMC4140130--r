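Package: enrichIFS
Title: Network-Neighborhood Enrichment Encoding and Incremental Feature
    Selection for Disease-Gene Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Encodes genes as vectors of functional-enrichment scores by
    testing each gene's closed interaction-network neighborhood against
    Gene Ontology terms and KEGG pathways with the hypergeometric
    upper-tail test, then discriminates disease-related from background
    genes through a staged feature-selection pipeline: Cramer's-V
    filtering of features against the class label, minimum-redundancy
    maximum-relevance (mRMR) ranking, and support-vector-machine driven
    incremental feature selection scored by the Matthews correlation
    coefficient under stratified cross-validation. Per-dataset optimal
    feature sets obtained from balanced negative subsamples are combined
    into a final optimal feature set with multiplicity and
    ontology-category summaries. Includes a synthetic-data generator
    that plants neighborhood-level enrichment signal so the whole
    pipeline can be validated without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    igraph,
    Matrix,
    e1071,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'aggregate.R'
    'cramer.R'
    'io.R'
    'synthetic.R'
    'datasets.R'
    'enrichIFS-package.R'
    'enrichment.R'
    'ifs.R'
    'mrmr.R'
    'pipeline.R'
    'show-methods.R'
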