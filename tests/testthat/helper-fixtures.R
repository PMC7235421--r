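# Shared builders for test inputs.

make_db <- function(df, name = "db", weight = 1) {
  marker_db(df, name = name, weight = weight)
}

tcell_db <- function() {
  make_db(data.frame(
    cell_type = c("T cell", "T cell", "T cell", "B cell", "B cell", "NK cell"),
    gene = c("CD3D", "CD3E", "IL7R", "CD19", "MS4A1", "NKG7"),
    count = c(4L, 8L, 2L, 6L, 3L, 5L)
  ))
}

# Run the package pipeline on a one-cluster instance and return the full
# uniform score vector (top_n large enough to keep every candidate).
pipeline_uniform <- function(degs, dbs, weights, bias = 0,
                             lfc_min = 1, p_max = 0.05) {
  tab <- deg_table(degs$gene, "c1", degs$lfc, degs$pvalue)
  db_objs <- lapply(seq_along(dbs), function(i)
    make_db(dbs[[i]], name = paste0("db", i)))
  res <- annotate(tab, db_objs, spec = weight_spec(weights, bias),
                  lfc_min = lfc_min, p_max = p_max, top_n = 1000L)[["c1"]]
  if (res$status == "unresolved") return(NULL)
  setNames(res$ranking$score, res$ranking$cell_type)
}

# Planted-truth end-to-end run; returns TRUE per cluster iff top-1 == truth.
recovery_hits <- function(seed, noise = 0, overlap = 0) {
  spec <- fixture_spec(n_cell_types = 5, markers_per_type = 5,
                       overlap_fraction = overlap,
                       noise_gene_fraction = noise, seed = seed)
  gen <- generate_marker_db(spec)
  truth <- setNames(names(gen$markers), as.character(seq_len(5)))
  degs <- generate_deg_table(gen, truth, spec)
  res <- annotate(degs, gen$db)
  vapply(names(truth), function(cl) {
    r <- res[[cl]]
    nrow(r$ranking) > 0 && r$ranking$cell_type[1] == truth[[cl]]
  }, TRUE)
}

expect_named_equal <- function(got, want, tol = 1e-9) {
  expect_setequal(names(got), names(want))
  expect_equal(as.numeric(got[names(want)]), as.numeric(want),
               tolerance = tol, ignore_attr = TRUE)
}
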