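Package: crgnet
Title: Prioritizing Chemosensitivity-Related Genes with Gene Ontology and
    Protein-Interaction-Network Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies chemosensitivity-related genes (CRGs) from
    drug-activity and gene-expression screens of tumor cell-line panels by
    combining three filters seeded on a curated compendium of known
    drug-gene pairs: membership in Gene Ontology terms enriched among the
    curated genes (depth-limited Fisher exact test), top-fraction degree and
    betweenness centrality in a protein-interaction network, and an
    absolute Pearson-correlation threshold set at a percentile of the
    curated pairs' correlations. Surviving genes are ranked by fusing
    degree and betweenness ranks with the Q order statistic. Includes a
    seeded synthetic-data generator with planted ground truth, permutation
    null models for centrality, hypergeometric and ROC/AUC evaluation
    against a matched-count correlation-only baseline, and a command-line
    entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
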