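Package: lncscape
Title: Paired lncRNA-mRNA Expression Landscape Analysis with Cis and
    Trans Target Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis workflow for paired tumor/normal lncRNA and mRNA
    microarray profiles: paired differential expression with the
    fold-change/p/FDR triple filter, lncRNA-mRNA Pearson co-expression
    networks, cis target assignment by a genomic window rule, trans
    regulator inference by hypergeometric overlap with transcription
    factor target sets, typed TF-lncRNA(-mRNA) network export, qPCR
    2^-ddCt relative quantification, chi-square clinicopathological
    association and median-split Kaplan-Meier survival analysis. Ships
    a synthetic-data generator with a machine-readable truth record so
    the whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    survival,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
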