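Package: tfdep
Title: Transcription-Factor Dependence Analysis for Two-Background RNA-Seq
    Induction Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to ask whether a stimulus-induced transcriptional response
    depends on a transcriptional regulator by comparing gene induction between
    two genetic backgrounds (for example wild-type versus knockout mast cells
    activated through the IgE receptor). Implements induction fold-change
    classification from count or FPKM matrices, the fold-change-difference
    dependence regression with an iterative Euclidean-distance point filter,
    hypergeometric gene-set enrichment with Bonferroni adjustment, expression
    normalization (CPM, FPKM, TPM), and a negative-binomial simulator with
    per-gene ground truth so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
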