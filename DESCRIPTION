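Package: osteomiR
Title: Prognostic 14q32 miRNA Signatures, Molecular Subtypes, and
    miRNA-Aware Regulatory Networks in Osteosarcoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of an integrative osteosarcoma
    analysis pipeline centred on the imprinted 14q32 (DLK1-DIO3) miRNA
    cluster: signed-average prognostic scoring with leave-one-out
    cross-validation and ridge-penalized Cox regression, time-dependent ROC
    evaluation with permutation p-values and random-profile baselines,
    molecular-subtype discovery (average-linkage clustering, classical MDS,
    differential expression with Benjamini-Hochberg FDR and a random-splits
    null, KS/LS functional class scoring), CTCF-context methylation versus
    expression correlation analysis, and PUMA message-passing gene-regulatory
    network inference with permuted-background edge significance and a
    gene-drug interaction screen. A synthetic-data module generates cohorts,
    methylation panels, cell-line panels and planted regulatory networks with
    the statistical structure the analysis assumes, so every stage is
    testable without access to the original cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    IRanges,
    GenomicRanges,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    mclust,
    limma,
    optparse,
    jsonlite
Config/testthat/edition: 3
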