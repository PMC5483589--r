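Package: modstrat
Title: Signaling-Network Module Signatures and Survival Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrates differential-expression target lists with signed
    directed signaling networks to extract Steiner-tree-connected pathway
    modules, tests gene-set enrichment by over-representation and rank-based
    procedures, stratifies patients by module-gene expression using
    correlation-distance complete-linkage clustering with a dynamic hybrid
    dendrogram cut, compares metastasis-free survival between clusters with
    Kaplan-Meier and log-rank analyses, and calibrates a signature's
    prognostic value against a random-signature resampling null. Ships
    seeded synthetic generators for every input so the whole chain runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    survival,
    limma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
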