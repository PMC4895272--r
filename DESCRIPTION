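Package: mircore
Title: Discovery of miRNA-mRNA Regulatory Modules as Collective Group
    Relationships
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies miRNA-mRNA regulatory modules from matched
    expression profiles by mining a correlation-weighted bipartite
    miRNA-mRNA graph. Pairwise Pearson correlations between miRNA and
    mRNA expression define interaction weights; collaboration scores
    summarise how strongly two miRNAs (or two mRNAs) share weighted
    interactions with the other side; a greedy overlapping
    neighbourhood-expansion clustering maximising a cohesiveness
    objective groups each side separately; and canonical correlation
    analysis scores every (miRNA group, mRNA group) pair, ranking
    significant pairs as collective group relationships (COREs).
    Includes a planted-module synthetic data generator, a reference
    interaction validator, and classical, ridge and sparse
    (penalized-matrix-decomposition) canonical correlation solvers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
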