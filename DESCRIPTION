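Package: scmodnet
Title: Marker Detection, Co-Expression Modules and Module-Cluster
    Inference for Single-Cell Atlases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream statistical machinery for a clustered single-cell
    RNA-seq atlas: cell-level quality-control filtering, log
    library-size normalization and variable-gene selection, dual marker
    gene detection (Wilcoxon rank-sum markers and a strict
    detection-fraction specificity rule), gene-set enrichment of
    markers, robust weighted gene co-expression network construction
    (biweight midcorrelation, soft thresholding, topological overlap,
    dendrogram module detection, module eigengenes and eigengene-based
    merging), and two permutation-based procedures linking gene modules
    to cell clusters: eigengene t-statistic association and
    leave-cluster-out connectivity sensitivity. Includes a seeded
    synthetic-atlas generator with planted markers and latent-factor
    co-expression modules so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
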