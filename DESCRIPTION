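Package: paritysig
Title: Discovery and Transfer of Parity-Associated Gene Expression Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering a gene expression signature of parity
    (having given birth) in normal breast tissue and testing its transfer
    into independent tumor / cancer-adjacent cohorts. Implements two-class
    SAM-style differential expression with a fudge factor and permutation
    false discovery rate, average-linkage clustering with cluster-based
    parity prediction accuracy, a weighted running-sum gene set enrichment
    score with phenotype-permutation family-wise error rate, the Creighton
    correlation-template sample classifier, and 2x2 odds-ratio association
    statistics with Wald intervals and chi-square or Fisher tests. A
    synthetic-cohort generator reproduces the statistical structure of the
    training (nulliparous vs parous mammoplasty) and test (paired
    adjacent-normal and tumor tissue, stratified by estrogen receptor
    status) designs so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
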