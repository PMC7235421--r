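---
title: "The scTypeScore annotation model: assumptions, parameters, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The scTypeScore annotation model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scTypeScore)
```

## The problem

After unsupervised clustering of single-cell RNA-seq data, each cluster must
be assigned a biological identity. `scTypeScore` automates the
cluster-then-annotate convention: it consumes each cluster's differential
expression summary (log2 fold change and p-value per gene, cluster vs rest)
and one or more curated marker databases in which every (cell type, gene)
pair carries an evidence count `a` — the number of literature references
supporting that marker relationship. The annotation unit is the cluster; no
per-cell calls are made.

## The score model, stage by stage

**Filtering.** Genes of a cluster with `lfc >= lfc_min` and `pvalue <= p_max`
are its marker candidates. Defaults `lfc_min = 1`, `p_max = 0.05`. The filter
is one-sided on LFC by design: down-regulation is not marker evidence for the
cluster itself. Two alternative profiles are conventional: `lfc_min = 1.5`
for CellRanger-preprocessed PBMC runs, and `p_max = 0.001` paired with the
built-in t-test DEG path (`compute_degs()`).

**Gene weights.** `e_j = |LFC_j| * mean(|LFC|)` over the filtered list. The
phrase "mean of all" in the source description is ambiguous; we fix it as the
mean of the cluster's own filtered |LFC| values — the only vector in scope of
that sentence. The choice is consequence-free for rankings: any
cluster-constant factor scales raw scores uniformly and cancels in the
z-scoring stage (this is tested as a rescaling invariance).

**Evidence matrix.** Nonzero entries are `log2(a) + 0.05`, applying the
constant after the log (the constant is described as added to the transformed
value). This damps the range between heavily and thinly referenced markers
while keeping `a = 1` markers visible at 0.05.

**Style vector.** `l = std * num`, where `num` counts the cell type's matched
markers and `std` is the *population* standard deviation of their transformed
evidence values. Zeros in the matrix are structural absences, not
observations, so they never enter the std. Two deliberate edge rules:

- A single-marker cell type has no spread; the literal formula would zero it
  out and make one-marker types permanently unannotatable. We replace the std
  factor by 1, giving `l = num = 1`.
- A multi-marker cell type whose evidence counts are all equal keeps
  `l = 0`: the formula genuinely assigns it no style weight, and we document
  rather than patch that consequence. In particular, a database in which
  every count is 1 yields flat 0.05 matrices and all-zero styles.

A related caution: raw scores are **not** monotone in a single evidence
count for multi-marker cell types. Raising a low count toward the row's other
counts shrinks the spread faster than it grows the evidence mass, and the raw
score can drop. Monotonicity holds in each marker's LFC (all else fixed), and
in the count for single-marker rows; only those two properties are asserted.

**Raw scores, normalization, harmonization, merging.** Per database,
`s_i = (sum_j M[i,j] e_j) * l_i`. Each database's score vector is z-scored
across its candidate cell types using the sample standard deviation
(denominator `p - 1`). Normalization is per cluster per database — the score
vector is indexed by cell type, so that is the axis standardized; we
normalize *before* extending to the union, matching the order of the staged
equations. Vectors are then zero-filled onto the lexicographically sorted
union of all databases' candidates (a missing cell type is "no signal", which
after z-scoring is exactly 0) and merged as `S' = sum_k w_k Z'_k + b`.
Defaults: cell-type databases `w = 1`, functional-state databases (CancerSEA
style) `w = 0.5` so that states inform but never dominate type calls, and
`b = 0` — the bias has no published value and only shifts all scores equally.

**Ranking and confidence.** Cell types are sorted by score, ties broken
alphabetically for determinism. Confidence is an artifact decision, not part
of the source model: scores are shifted so the reported minimum is 0.001
(ratios of signed z-scores are meaningless) and the call is `confident` when
top/runner-up exceeds `ambiguity_ratio` (default 2) or only one candidate
exists with a well-defined score. Degenerate z-scores (one candidate, or zero
variance) produce all-zero vectors, a degeneracy flag, and at most an
`ambiguous` call; `unresolved` is reserved for clusters with no marker
evidence in any database, which are routed to the GO fallback.

## The t-test DEG path

When given a raw expression matrix plus cluster labels, `compute_degs()` runs
a classical two-sample, two-sided, pooled-variance Student's t-test per gene
(cluster vs rest) and reports `LFC = log2((mean_in + 1)/(mean_out + 1))`. The
pseudocount of 1 (on the supplied expression scale) is the standard guard
against log of zero; no value is published for it. Zero pooled variance is
resolved as p = 1 for identical constants and p = 0 for separated constants.
Clusters with fewer than two cells on either side are skipped with a warning,
never silently dropped.

## The GO enrichment fallback

For an unresolved cluster, each GO term is tested with a one-sided Fisher's
exact test: foreground = the cluster's filtered DEGs, background = the
filtered DEGs of all other clusters, with three fixed conventions. Genes in
both sets are removed from the background (the split by cluster implies
disjointness; shared DEGs would double-count). The universe is restricted to
genes present in the gene-to-term map, because unannotated genes cannot
inform term enrichment either way. The test is one-sided (upper tail of the
hypergeometric) because depletion of a term is not evidence about a cluster's
function. P-values are Benjamini–Hochberg adjusted
(`q_(i) = min_{j>=i} m p_(j)/j`, clipped at 1) and terms with `q <= q_max`
(default 0.05, a community convention) are reported.

## What the synthetic fixtures emulate — and what they do not

`fixture_spec()` describes a planted world: `n_cell_types` synthetic types
with `markers_per_type` markers each, optional marker sharing between
adjacent types (`overlap_fraction`, floor semantics: 0.2 of 5 markers = 1
shared gene), evidence counts uniform on `evidence_count_range` (default
1–10, the realistic span of reference counts for curated markers), cluster
DEG lists that are the true type's markers with |LFC| uniform on
`lfc_range` (default 1.5–4, comfortably above the filter) and p uniform on
(0, 0.01], plus `floor(noise_gene_fraction * markers_per_type)` noise genes
per cluster (half wrong-type markers, half symbols absent from any database).
The expression generator adds a fixed log-scale effect (default 3 log2 units,
noise sd 0.5, 20 cells per cluster) to the true type's markers.

These fixtures target the annotation *math*. They have none of the texture of
real scRNA-seq data: no dropout, no library-size variation, no correlated
genes, no mis-clustered cells, and marker databases that are complete and
correct by construction. A green recovery test therefore establishes that the
scoring pipeline is implemented faithfully and is robust to the modeled noise
— not that any particular accuracy will be achieved on real tissue with an
incomplete marker catalog.

All fixture randomness flows through one seed per generator call, and the
caller's RNG state is restored afterwards.

## Numerical choices

- Scoring is fully deterministic; only fixture generation consumes
  randomness.
- Population std (divide by n) in the style vector; sample std (divide by
  p − 1) in z-scoring — each matching its defining formula.
- Duplicate (gene, cluster) rows keep the maximum-|LFC| record, ties broken
  by smaller p-value, preserving the strongest evidence.
- Gene symbols are matched literally after uppercasing and quote-stripping;
  no ortholog or identifier mapping.
- Cluster labels are always strings, so labels like "1a" survive round-trips.
- The CellRanger dialect is dense by construction; absent (gene, cluster)
  cells are written as LFC 0, p 1, which cannot pass any admissible filter.
- Fisher tail probabilities come from the hypergeometric distribution
  (`stats::phyper`); tests verify them against exhaustive fixed-margin
  enumeration built from binomial coefficients, to 1e-12 for all table sizes
  up to N = 60.

## Known limitations

- Annotation quality is bounded by marker-database coverage; types without
  curated markers can only ever reach the GO fallback.
- The confidence call (ratio rule) is a heuristic with no published
  counterpart; treat `confident`/`ambiguous` as a triage signal.
- The GO fallback tests a pre-flattened gene-to-term map; there is no
  ontology graph propagation, so parent terms are not credited with
  descendant annotations.
- No clustering, dimensionality reduction, or per-cell assignment is
  provided or planned.
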