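Package: cofea
Title: Correlation-Based Feature Selection for Single-Cell Chromatin Accessibility Data
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Selects informative peaks from single-cell chromatin accessibility
    (scCAS/scATAC-seq) peak-by-cell count matrices. The method applies TF-IDF
    normalisation and a cell-wise principal component analysis to obtain a
    peak-by-PC embedding, summarises every peak by the mean and mean square of
    its correlation coefficients with all other peaks (computed blockwise,
    without materialising the peak-by-peak matrix), and scores peaks by their
    absolute residual from an iteratively trimmed LOWESS fit of mean square
    against mean. Also provides simulators for synthetic scCAS datasets with
    planted cell type-specific peaks, dropout injection, baseline selectors
    (highest degree of accessibility, Signac-style, epiScanpy-style), and a
    clustering-based evaluation harness (NMI, AMI, ARI, homogeneity, ASW,
    cLISI) with a Leiden clustering pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    parallel,
    irlba,
    igraph,
    cluster,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
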