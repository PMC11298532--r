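Package: sctab
Title: Cross-Tissue Cell-Type Annotation with Feature-Attention Tabular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for annotating cell types in single-cell RNA-seq data across
    tissues with a feature-attention tabular neural network (a TabNet-style
    classifier with 1.5-entmax sparse feature attention and a single decision
    step), together with the surrounding workflow: Cell Ontology loading and
    subtype reasoning, corpus filtering and donor-based splitting, donor
    difference-vector data augmentation, ontology-corrected macro F1
    evaluation with fine-to-coarse label mapping, deep-ensemble uncertainty
    scores, linear and multi-layer perceptron baselines, a chunked Parquet
    batch stream for out-of-core corpora, and a seeded synthetic-data
    generator used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    arrow,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
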