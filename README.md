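# scTypeScore

Automatic cell-type annotation for clustered single-cell RNA-seq data.

Unsupervised clustering tells you *that* a group of cells is coherent, not
*what* it is. The usual next step — eyeballing each cluster's differentially
expressed genes (DEGs) against marker lists from the literature — is slow and
irreproducible. `scTypeScore` replaces it with a scoring model that combines
two kinds of evidence per cluster:

- **expression enrichment**: how strongly each filtered DEG is up-regulated
  (its log2 fold change), and
- **reference evidence**: how well-supported each (cell type, gene) marker
  relationship is in one or more curated databases (a count of supporting
  references, CellMarker-style).

## The model

For each cluster, DEGs passing `LFC >= lfc_min` and `P <= p_max` (defaults 1
and 0.05) define a gene weight vector with entries
`e_j = |LFC_j| * mean(|LFC|)`. For each database *k*, the cluster's genes that
are also markers give a cell-gene evidence matrix `M_k` whose nonzero entries
are `log2(a) + 0.05` for an evidence count `a`, and a per-cell-type style
vector `L_k` with `l = std(evidence) * num(markers)` (population std over the
matched markers; a single-marker cell type gets std factor 1). The raw score
of a cell type is

```
s_i = ( sum_j M_k[i, j] * e_j ) * l_i
```

Raw score vectors are z-scored across candidate cell types (sample sd),
zero-filled onto the sorted union of all databases' candidates, and merged as
`S' = sum_k w_k * Z'_k + b` with per-database weights `w` and bias `b`
(defaults: each database's own weight, `b = 0`). Cell types are ranked by the
uniform score `S'`; clusters whose DEGs match no database are flagged
`unresolved` and fall back to a per-GO-term Fisher's exact enrichment
(one-sided, foreground = the cluster's DEGs, background = all other clusters'
DEGs) with Benjamini–Hochberg correction.

## Worked example

A small synthetic reference database in the CellMarker-like schema
(`species, tissue, cell_type, gene_symbol, ref_count`) ships with the package;
real CellMarker/CancerSEA exports in the same five-column layout are drop-in
replacements.

```r
library(scTypeScore)

ref <- load_reference_db(
  system.file("extdata", "synthetic_cellmarker.tsv", package = "scTypeScore"),
  species = "human")

degs <- deg_table(
  gene    = c("CD14", "LYZ", "S100A8", "S100A9", "FCGR3A", "FCN1",
              "CD3D", "CD3E", "IL7R", "TRAC"),
  cluster = c(rep("0", 6), rep("1", 4)),
  lfc     = c(2.8, 3.5, 2.2, 2.0, 1.6, 1.9, 2.4, 3.1, 1.8, 2.0),
  pvalue  = c(1e-12, 1e-15, 1e-8, 1e-7, 1e-4, 1e-6, 1e-10, 1e-14, 1e-5, 1e-6))

res <- annotate(degs, ref, top_n = 3)
print(res[["0"]]); print(res[["1"]])
```

prints

```
cluster 0 [confident]
  1. Monocyte                           0.7071
  2. Macrophage                        -0.7071
cluster 1 [ambiguous]
  1. T cell                             0.0000
```

Cluster 0's DEGs hit markers of both Monocyte and Macrophage (they share LYZ
and FCGR3A), but the monocyte evidence is broader and stronger, so Monocyte
gets the higher z-score and the call is `confident`. Cluster 1 matches only
T-cell markers: a single candidate cannot be z-scored (degenerate, score 0),
so it is reported but flagged `ambiguous`. Scores are z-scores merged across
databases — their scale is relative ranking evidence within a cluster, not an
absolute probability.

Typical file-based use reads `Seurat::FindAllMarkers` output or a CellRanger
differential-expression CSV instead of an inline table:

```r
cfg <- run_config("markers.csv", dialect = "seurat",
                  dbs = "my_markers.tsv", term_map = "go_map.tsv",
                  out_dir = "out")
run_annotation(cfg)   # writes out/annotation.tsv (+ out/go_enrichment.tsv)
```

or from the shell via the bundled launcher:

```sh
Rscript inst/scripts/scTypeScore annotate \
  --input markers.csv --dialect seurat --db my_markers.tsv:1 \
  --term-map go_map.tsv --out out
```

Subcommands `fixtures` (synthetic planted-truth bundles) and `enrich`
(standalone GO enrichment) are also available.

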