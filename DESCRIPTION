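Package: scTypeScore
Title: Score-Based Cell Type Annotation for Clustered Single-Cell RNA-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automatic cell-type annotation of pre-clustered single-cell
    RNA-seq data. Per-cluster differential-expression tables (CellRanger or
    Seurat dialects) are filtered on log2 fold change and p-value, matched
    against one or more marker-gene reference databases carrying literature
    evidence counts, and scored by a model that combines expression enrichment
    with evidence strength. Scores from multiple databases are z-score
    normalized, harmonized over the union of candidate cell types, and merged
    with configurable weights. Clusters without marker evidence fall back to a
    Fisher's exact GO-term enrichment with Benjamini-Hochberg correction.
    Includes a synthetic fixture generator with planted ground truth and a
    command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
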