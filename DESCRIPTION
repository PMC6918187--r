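Package: acorf
Title: Analytic Correlation Filtration of MS Metabolomics Feature Tables
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects analytical redundancy in LC- and GC-MS metabolomics
    peak tables. Features (ions) derived from the same analyte -- isotopologues,
    adducts and in-source fragments -- are grouped using three independent
    criteria: a pairwise intensity-profile similarity threshold, a retention
    time window, and matching of mass differences against a reference list of
    known isotope/adduct/fragment deltas. One representative feature is then
    selected per group (four selection methods) and redundant features are
    flagged for filtration. Reads and writes Workflow4Metabolomics-style
    tabular files (data matrix, variable metadata, similarity matrix) and
    exports Cytoscape SIF correlation networks. Includes a synthetic peak-table
    generator with ground-truth analyte groups for validation, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    igraph,
    mclust,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
Collate: 
    'AllGenerics.R'
    'AllClasses.R'
    'acorf-package.R'
    'grouping.R'
    'io.R'
    'representative.R'
    'pipeline.R'
    'similarity.R'
    'simulate.R'
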