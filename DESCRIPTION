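Package: dctyper
Title: Multi-Modal Consensus Annotation of Dendritic-Cell Types from
    Index-Sorted Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Annotates dendritic-cell types (pDC, pDC-like, transitional DC,
    cDC1, cDC2) and activation states in plate-based, index-sorted single-cell
    RNA-seq data by combining two independent clusterings -- a
    transcriptome-based kNN-Jaccard/Louvain partition and a PhenoGraph-style
    partition of arcsinh-transformed surface-marker intensities -- with
    per-cell connectivity-map (Kolmogorov-Smirnov) enrichment scores against
    composite UP/DN cell-type signatures derived from bulk reference
    profiles.  Cells are assigned a final type only when the two modalities
    agree (with deductive reassignment when one modality is unresolved),
    contaminant clusters (macrophages, NK cells, proliferating cells) are
    detected and removed via gene-module scores, activation states
    (quiescent, intermediate, activated, IFN-producing) are labeled from ISG,
    maturation, cytokine and interferon modules, and pairwise differential
    expression is computed with Wilcoxon rank-sum tests under Bonferroni
    correction.  A ground-truthed negative-binomial simulator of
    index-sorted DC data supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
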