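# ---- local RNG scope -------------------------------------------------------

# Run `code` under `seed` and restore the caller's RNG state afterwards, so
# fixture generation never perturbs a surrounding simulation.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# ---- FixtureSpec -----------------------------------------------------------

#' Specification of a synthetic annotation fixture
#'
#' Describes a planted world: `n_cell_types` synthetic cell types, each with
#' `markers_per_type` marker genes of which `floor(overlap_fraction *
#' markers_per_type)` are shared with the next cell type (cyclically);
#' evidence counts drawn uniformly from `evidence_count_range`; `n_clusters`
#' clusters whose DEG lists are their true type's markers with |LFC| uniform
#' in `lfc_range` and p uniform in (0, 0.01], plus
#' `floor(noise_gene_fraction * markers_per_type)` off-target noise genes.
#'
#' @param n_cell_types integer >= 2.
#' @param markers_per_type integer >= 1.
#' @param overlap_fraction real in \[0, 1).
#' @param evidence_count_range integer pair (low, high), low >= 1.
#' @param n_clusters integer >= 1 (default: one per cell type).
#' @param noise_gene_fraction real in \[0, 1).
#' @param lfc_range positive real pair.
#' @param seed integer seed; every generator call is deterministic under it.
#' @return a `fixture_spec`.
#' @export
fixture_spec <- function(n_cell_types = 5, markers_per_type = 5,
                         overlap_fraction = 0, evidence_count_range = c(1, 10),
                         n_clusters = n_cell_types, noise_gene_fraction = 0,
                         lfc_range = c(1.5, 4), seed = 1) {
  stopifnot(n_cell_types >= 2, markers_per_type >= 1,
            overlap_fraction >= 0, overlap_fraction < 1,
            length(evidence_count_range) == 2,
            evidence_count_range[1] >= 1,
            evidence_count_range[2] >= evidence_count_range[1],
            n_clusters >= 1,
            noise_gene_fraction >= 0, noise_gene_fraction < 1,
            length(lfc_range) == 2, lfc_range[1] > 0,
            lfc_range[2] >= lfc_range[1])
  structure(list(n_cell_types = as.integer(n_cell_types),
                 markers_per_type = as.integer(markers_per_type),
                 overlap_fraction = overlap_fraction,
                 evidence_count_range = as.integer(evidence_count_range),
                 n_clusters = as.integer(n_clusters),
                 noise_gene_fraction = noise_gene_fraction,
                 lfc_range = as.numeric(lfc_range),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

# ---- marker database generator ---------------------------------------------

#' Generate a synthetic marker database with planted ground truth
#'
#' Cell types CT1..CTn carry disjoint marker sets of synthetic genes
#' (SYNG0001, ...); when `overlap_fraction > 0`, each type's last
#' `floor(overlap_fraction * markers_per_type)` markers are replaced by the
#' next type's leading markers (cyclic), emulating shared markers between
#' related cell types.
#'
#' @param spec a [fixture_spec()].
#' @return list with `db` (a [marker_db()]) and `markers` (named list:
#'   cell type -> its marker genes, the ground truth).
#' @export
generate_marker_db <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_cell_types
  m <- spec$markers_per_type
  n_shared <- floor(spec$overlap_fraction * m + 1e-9)
  if (spec$overlap_fraction > 0 && n_shared < 1) {
    stop("generate_marker_db: infeasible overlap: ",
         "overlap_fraction * markers_per_type rounds to zero shared markers")
  }
  if (n_shared >= m) stop("generate_marker_db: overlap leaves no private markers")
  with_seed(spec$seed, {
    pool <- sprintf("SYNG%04d", seq_len(n * m))
    own <- split(pool, rep(seq_len(n), each = m))
    markers <- own
    if (n_shared > 0) {
      for (i in seq_len(n)) {
        nxt <- if (i == n) 1L else i + 1L
        markers[[i]] <- c(own[[i]][seq_len(m - n_shared)],
                          own[[nxt]][seq_len(n_shared)])
      }
    }
    names(markers) <- sprintf("CT%d", seq_len(n))
    entries <- data.frame(
      cell_type = rep(names(markers), lengths(markers)),
      gene = unlist(markers, use.names = FALSE),
      count = sample(seq(spec$evidence_count_range[1],
                         spec$evidence_count_range[2]),
                     n * m, replace = TRUE),
      stringsAsFactors = FALSE
    )
    list(db = marker_db(entries, name = "synthetic", weight = 1),
         markers = markers)
  })
}

# ---- DEG table generator ---------------------------------------------------

#' Generate a DEG table with planted cluster identities
#'
#' Cluster `c`'s DEGs are the markers of `truth[c]` with |LFC| uniform in
#' `lfc_range` and p uniform in (0, 0.01], so every planted gene survives the
#' default filter. Noise genes (half markers of a wrong type, half novel
#' symbols absent from the database) are appended at
#' `floor(noise_gene_fraction * markers_per_type)` per cluster.
#'
#' @param db_truth list from [generate_marker_db()] (`db` + `markers`).
#' @param truth named character vector: cluster label -> planted cell type.
#' @param spec the [fixture_spec()].
#' @return a [deg_table()] (dialect "generic").
#' @export
generate_deg_table <- function(db_truth, truth, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  markers <- db_truth$markers
  stopifnot(all(truth %in% names(markers)))
  n_noise <- floor(spec$noise_gene_fraction * spec$markers_per_type + 1e-9)
  with_seed(spec$seed + 1L, {
    rows <- lapply(names(truth), function(cl) {
      genes <- markers[[truth[[cl]]]]
      if (n_noise > 0) {
        wrong <- setdiff(unlist(markers[setdiff(names(markers), truth[[cl]])],
                                use.names = FALSE), genes)
        noise <- character(n_noise)
        for (i in seq_len(n_noise)) {
          noise[i] <- if (stats::runif(1) < 0.5 && length(wrong)) {
            pick <- sample(wrong, 1)
            wrong <- setdiff(wrong, pick)
            pick
          } else {
            sprintf("NOISEG%s_%03d", cl, i)
          }
        }
        genes <- c(genes, noise)
      }
      data.frame(gene = genes, cluster = cl,
                 lfc = stats::runif(length(genes), spec$lfc_range[1],
                                    spec$lfc_range[2]),
                 pvalue = stats::runif(length(genes), 1e-12, 0.01),
                 stringsAsFactors = FALSE)
    })
    all <- do.call(rbind, rows)
    deg_table(all$gene, all$cluster, all$lfc, all$pvalue, dialect = "generic")
  })
}

# ---- expression matrix generator -------------------------------------------

#' Generate a log-scale expression matrix with planted cluster structure
#'
#' Every gene gets a Gaussian baseline on the log scale; markers of a
#' cluster's true cell type are shifted upward by `effect_size` log2 units in
#' that cluster's cells. This targets the t-test DEG path, not scRNA-seq
#' realism (no dropout or library-size structure).
#'
#' @param db_truth list from [generate_marker_db()].
#' @param truth named character vector: cluster -> cell type.
#' @param spec the [fixture_spec()].
#' @param cells_per_cluster cells per cluster, default 20.
#' @param effect_size marker up-shift in log2 units, default 3.
#' @param noise_sd Gaussian noise standard deviation, default 0.5.
#' @param baseline mean background expression, default 1.
#' @param n_background extra non-marker genes, default 20.
#' @return list with `expr` (genes x cells matrix) and `labels`.
#' @export
generate_expression <- function(db_truth, truth, spec, cells_per_cluster = 20,
                                effect_size = 3, noise_sd = 0.5, baseline = 1,
                                n_background = 20) {
  stopifnot(inherits(spec, "fixture_spec"), cells_per_cluster >= 2)
  markers <- db_truth$markers
  genes <- c(sort(unique(unlist(markers, use.names = FALSE))),
             sprintf("BGRD%04d", seq_len(n_background)))
  clusters <- names(truth)
  n_cells <- cells_per_cluster * length(clusters)
  with_seed(spec$seed + 2L, {
    expr <- matrix(stats::rnorm(length(genes) * n_cells, mean = baseline,
                                sd = noise_sd),
                   nrow = length(genes), dimnames = list(genes, NULL))
    labels <- rep(clusters, each = cells_per_cluster)
    for (cl in clusters) {
      mk <- markers[[truth[[cl]]]]
      expr[mk, labels == cl] <- expr[mk, labels == cl] + effect_size
    }
    expr[expr < 0] <- 0
    list(expr = expr, labels = labels)
  })
}

#' Write a complete fixture bundle to disk
#'
#' Emits the files the readers consume: the DEG table in both the CellRanger
#' and Seurat dialects, the marker database as a two-column user TSV, the
#' reference-schema TSV, and a small term map over the synthetic genes.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, named character vector of the written paths.
#' @export
write_fixture_bundle <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_marker_db(spec)
  truth <- stats::setNames(names(gen$markers)[
    rep_len(seq_len(spec$n_cell_types), spec$n_clusters)],
    as.character(seq_len(spec$n_clusters)))
  degs <- generate_deg_table(gen, truth, spec)
  paths <- c(
    cellranger = file.path(dir, "degs_cellranger.csv"),
    seurat = file.path(dir, "degs_seurat.csv"),
    user_db = file.path(dir, "markers_user.tsv"),
    reference_db = file.path(dir, "markers_reference.tsv"),
    term_map = file.path(dir, "term_map.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_cellranger_diffexp(degs, paths[["cellranger"]])
  write_seurat_markers(degs, paths[["seurat"]])
  ent <- gen$db$entries
  utils::write.table(ent[rep(seq_len(nrow(ent)), ent$count),
                         c("cell_type", "gene")],
                     paths[["user_db"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(species = "human", tissue = "Synthetic",
                                cell_type = ent$cell_type,
                                gene_symbol = ent$gene,
                                ref_count = ent$count),
                     paths[["reference_db"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  # one synthetic term per cell type covering its markers
  tm <- data.frame(
    gene = unlist(gen$markers, use.names = FALSE),
    term = rep(sprintf("SYNT:%04d", seq_along(gen$markers)),
               lengths(gen$markers)),
    name = rep(sprintf("synthetic program of %s", names(gen$markers)),
               lengths(gen$markers))
  )
  utils::write.table(tm, paths[["term_map"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(cluster = names(truth), cell_type = truth),
                     paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
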