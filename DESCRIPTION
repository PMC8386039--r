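Package: ontozoo
Title: Ontology-Aware Cell-Type Classification and Embedding Model Zoo for Single-Cell Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for training and sharing cell-type classifiers and
    embedding models on single-cell RNA-seq count matrices whose labels
    follow a cell-type ontology. Classifiers are trained with an
    aggregated cross-entropy that pools predicted probability mass over
    the ontology descendants of a (possibly coarse) label, so datasets
    annotated at different granularities can be combined. Embedding
    models (linear, non-negative matrix factorization, autoencoder,
    variational autoencoder) are fitted with a negative-binomial
    reconstruction likelihood and compared against a sparse
    random-projection baseline. Includes gradient-map interpretation of
    encoder bottlenecks, an ontology-validated dataset registry with
    relational metadata queries and train/test splitting, a versioned
    model-parameter store, and a synthetic-data generator that produces
    ontologies, count matrices and metadata cards for fully offline
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    pheatmap,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
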