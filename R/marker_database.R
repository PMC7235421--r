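# ---- MarkerDatabase --------------------------------------------------------

#' Construct a marker-gene database
#'
#' A marker database maps (cell type, gene) pairs to an evidence count `a`:
#' the number of literature references supporting that marker relationship.
#' Duplicate (cell type, gene) entries in `entries` are aggregated by summing
#' their counts (tissues are structural provenance, not observations, so
#' counts pool across them).
#'
#' @param entries data.frame with columns `cell_type`, `gene`, `count`
#'   (and optionally `tissue`, `species`, used only for filtering upstream).
#' @param name source label, e.g. "cellmarker", "user".
#' @param species optional "human" or "mouse".
#' @param weight merge weight `w` for this database. Defaults to 1 for
#'   cell-type databases and 0.5 for functional-state collections
#'   (CancerSEA-style), which describe states rather than types and are kept
#'   sub-dominant but visible.
#' @param kind "cell_type" or "functional_state".
#' @return a `marker_db` object.
#' @export
marker_db <- function(entries, name = "user", species = NA_character_,
                      weight = NULL,
                      kind = c("cell_type", "functional_state")) {
  kind <- match.arg(kind)
  if (is.null(weight)) weight <- if (kind == "functional_state") 0.5 else 1
  stopifnot(is.data.frame(entries),
            all(c("cell_type", "gene", "count") %in% names(entries)))
  ct <- trimws(as.character(entries$cell_type))
  gn <- normalize_gene(entries$gene)
  cnt <- as.integer(entries$count)
  keep <- nzchar(ct) & nzchar(gn) & !is.na(cnt)
  ct <- ct[keep]; gn <- gn[keep]; cnt <- cnt[keep]
  if (!length(ct)) stop("marker_db: database has no valid entries")
  if (any(cnt < 1L)) stop("marker_db: evidence counts must be >= 1")
  agg <- stats::aggregate(list(count = cnt),
                          by = list(cell_type = ct, gene = gn), FUN = sum)
  agg <- agg[order(agg$cell_type, agg$gene), , drop = FALSE]
  rownames(agg) <- NULL
  structure(
    list(name = name, species = species, weight = as.numeric(weight),
         kind = kind, entries = agg),
    class = "marker_db"
  )
}

#' @export
print.marker_db <- function(x, ...) {
  cat(sprintf("marker_db '%s': %d cell types, %d (cell type, gene) entries, weight=%g\n",
              x$name, length(unique(x$entries$cell_type)), nrow(x$entries),
              x$weight))
  invisible(x)
}

#' Load a packaged-schema marker reference database
#'
#' Reads a TSV in the reference schema: columns `species`, `tissue`,
#' `cell_type`, `gene_symbol`, `ref_count` (header required). Rows are
#' restricted to the requested species and, optionally, tissues; evidence per
#' (cell type, gene) is the sum of reference counts over the surviving rows.
#'
#' @param path path to the reference TSV.
#' @param species "human" or "mouse".
#' @param tissue_filter optional character vector of tissues to keep
#'   (default: all tissues; the model annotates across tissues).
#' @param name database label, default "cellmarker".
#' @param weight merge weight, default 1.
#' @return a [marker_db()].
#' @export
load_reference_db <- function(path, species = c("human", "mouse"),
                              tissue_filter = NULL, name = "cellmarker",
                              weight = 1) {
  if (!is.character(species) || !all(species %in% c("human", "mouse"))) {
    stop("load_reference_db: unknown species token: ",
         paste(setdiff(as.character(species), c("human", "mouse")), collapse = ", "))
  }
  species <- match.arg(species)
  if (!file.exists(path)) stop("load_reference_db: no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "tissue", "cell_type", "gene_symbol", "ref_count")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols)) {
    stop("load_reference_db: reference table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab <- tab[tolower(tab$species) == species, , drop = FALSE]
  if (!is.null(tissue_filter)) {
    tab <- tab[tolower(tab$tissue) %in% tolower(tissue_filter), , drop = FALSE]
  }
  if (!nrow(tab)) {
    stop("load_reference_db: no entries left after species/tissue filtering")
  }
  marker_db(
    entries = data.frame(cell_type = tab$cell_type, gene = tab$gene_symbol,
                         count = tab$ref_count, stringsAsFactors = FALSE),
    name = name, species = species, weight = weight
  )
}

# ---- evidence transform ----------------------------------------------------

#' Transform a reference evidence count to a matrix weight
#'
#' Damps the gap between famous and obscure markers: a count of `a`
#' supporting references becomes `log2(a) + 0.05`. The additive constant
#' keeps single-reference markers (a = 1) visible at a small positive weight.
#'
#' @param a positive integer evidence count(s).
#' @return numeric vector of transformed weights, all > 0.
#' @export
evidence_transform <- function(a) {
  if (any(is.na(a)) || any(a < 1)) {
    stop("evidence_transform: evidence counts must be >= 1")
  }
  log2(a) + 0.05
}

# ---- evidence matrix -------------------------------------------------------

#' Build the per-cluster cell-gene evidence matrix
#'
#' Columns are the intersection of the cluster's filtered DEG genes with the
#' database's marker genes, in `cluster_genes` order; rows are the cell types
#' having at least one such marker. Entries are [evidence_transform()]ed
#' counts at marker positions and 0 elsewhere. An empty matrix (0 rows) means
#' "no marker evidence" and routes the caller to the GO fallback.
#'
#' @param db a [marker_db()].
#' @param cluster_genes character vector of the cluster's filtered DEG genes.
#' @return numeric matrix with cell types as rownames, genes as colnames.
#' @export
build_evidence_matrix <- function(db, cluster_genes) {
  stopifnot(inherits(db, "marker_db"))
  cluster_genes <- unique(normalize_gene(cluster_genes))
  cols <- cluster_genes[cluster_genes %in% db$entries$gene]
  if (!length(cols)) {
    return(matrix(numeric(), nrow = 0, ncol = 0,
                  dimnames = list(character(), character())))
  }
  hits <- db$entries[db$entries$gene %in% cols, , drop = FALSE]
  types <- sort(unique(hits$cell_type))
  M <- matrix(0, nrow = length(types), ncol = length(cols),
              dimnames = list(types, cols))
  M[cbind(match(hits$cell_type, types), match(hits$gene, cols))] <-
    evidence_transform(hits$count)
  M
}

# ---- style vector ----------------------------------------------------------

#' Compute the per-cell-type style vector L
#'
#' For each cell type (row of the evidence matrix), `l` multiplies the
#' population standard deviation of its nonzero evidence entries by the
#' number of matched markers: `l = std(a_ij) * num(a_ij > 0)`. Zeros are
#' structural absences and never enter the standard deviation. A row with a
#' single matched marker has a degenerate std; its std factor is replaced by
#' 1 so one-marker cell types remain annotatable (`l = num`). A multi-marker
#' row whose evidence values are all equal keeps `l = 0`.
#'
#' @param M evidence matrix from [build_evidence_matrix()].
#' @return named numeric vector `l` aligned with `rownames(M)`.
#' @export
style_vector <- function(M) {
  if (!is.matrix(M) || nrow(M) == 0) {
    stop("style_vector: evidence matrix is empty")
  }
  vapply(seq_len(nrow(M)), function(i) {
    x <- M[i, ]
    x <- x[x > 0]
    n <- length(x)
    sd_factor <- if (n == 1L) 1 else sqrt(mean((x - mean(x))^2))
    sd_factor * n
  }, numeric(1)) -> l
  names(l) <- rownames(M)
  l
}
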