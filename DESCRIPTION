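Package: fetdeg
Title: Single-Replicate BeadChip Knockdown Expression Analysis with
    Multiscale-Bootstrap Cluster Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for single-replicate Illumina BeadChip siRNA
    knockdown experiments: quantile normalization, detection-p based probe
    filtering, negative-control background estimation, background-subtracted
    ratio calling of differentially expressed genes, multi-set Venn
    partitioning and hypergeometric overlap tests, standard-deviation gene
    selection with correlation-distance average-linkage clustering of samples
    and multiscale-bootstrap AU/BP cluster support, and efficiency-based X0
    quantification of RT-qPCR data. Includes a synthetic-data generator that
    emulates a six-array knockdown/control design with planted ground truth
    so every pipeline stage is testable at desk scale.
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
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
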