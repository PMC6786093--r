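Package: mircausal
Title: Causal miRNA-Disease Association Prediction by Label Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts causal microRNA-disease associations from a curated
    bipartite causal network by label propagation over integrated similarity
    kernels: MeSH-based disease semantic similarity, best-match-average miRNA
    functional similarity, Gaussian interaction profile kernels, and a
    hub-promoted-index adjustment. Includes evidence-code screening of
    HMDD-style association tables, a leakage-free hold-out and k-fold
    cross-validation protocol with ROC/AUC, a miRNA-conservation side
    analysis (causal disease number versus family size and precursor SNP
    load), and synthetic fixture generators for all input formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    optparse,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
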