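# ---- gene symbol / label normalization ------------------------------------

#' Normalize gene symbols
#'
#' Uppercases, strips surrounding whitespace and quotes. No ortholog or ID
#' mapping is performed; symbols are matched literally throughout the package.
#'
#' @param x character vector of raw gene symbols.
#' @return normalized character vector.
#' @export
normalize_gene <- function(x) {
  x <- gsub('^["\']+|["\']+$', "", trimws(as.character(x)))
  toupper(x)
}

normalize_cluster <- function(x) trimws(as.character(x))

# ---- DEGTable --------------------------------------------------------------

#' Construct a per-cluster differential-expression table
#'
#' The central input container: one row per (gene, cluster) with the gene's
#' log2 fold change (cluster vs rest) and p-value. Duplicate (gene, cluster)
#' rows are collapsed to the one with maximum |LFC|, ties broken by smaller
#' p-value, so the strongest marker evidence survives.
#'
#' @param gene character vector of gene symbols (normalized internally).
#' @param cluster cluster labels; always coerced to character so labels such
#'   as "1a" survive.
#' @param lfc numeric log2 fold changes.
#' @param pvalue numeric p-values in \[0, 1\].
#' @param mean_expr optional non-negative mean expression per record.
#' @param dialect one of "cellranger", "seurat", "generic".
#' @return a `deg_table`: a data.frame with columns gene, cluster, lfc,
#'   pvalue, mean_expr and attribute `source_dialect`.
#' @export
deg_table <- function(gene, cluster, lfc, pvalue, mean_expr = NA_real_,
                      dialect = "generic") {
  dialect <- match.arg(dialect, c("cellranger", "seurat", "generic"))
  if (!length(gene)) {
    df <- data.frame(gene = character(), cluster = character(),
                     lfc = numeric(), pvalue = numeric(),
                     mean_expr = numeric(), stringsAsFactors = FALSE)
    attr(df, "source_dialect") <- dialect
    class(df) <- c("deg_table", "data.frame")
    return(df)
  }
  df <- data.frame(
    gene = normalize_gene(gene),
    cluster = normalize_cluster(cluster),
    lfc = as.numeric(lfc),
    pvalue = as.numeric(pvalue),
    mean_expr = as.numeric(mean_expr),
    stringsAsFactors = FALSE
  )
  df <- df[nzchar(df$gene) & !is.na(df$lfc) & !is.na(df$pvalue), , drop = FALSE]
  if (nrow(df) && (any(df$pvalue < 0) || any(df$pvalue > 1))) {
    stop("deg_table: p-values must lie in [0, 1]")
  }
  df <- dedup_degs(df)
  rownames(df) <- NULL
  attr(df, "source_dialect") <- dialect
  class(df) <- c("deg_table", "data.frame")
  df
}

# Keep max |LFC| per (gene, cluster); ties -> smaller p. Original row order of
# the survivors is preserved.
dedup_degs <- function(df) {
  if (!nrow(df)) return(df)
  idx <- seq_len(nrow(df))
  o <- order(df$gene, df$cluster, -abs(df$lfc), df$pvalue, idx)
  keep <- o[!duplicated(df$gene[o] %+% "\r" %+% df$cluster[o])]
  df[sort(keep), , drop = FALSE]
}

`%+%` <- function(a, b) paste0(a, b)

#' @export
print.deg_table <- function(x, ...) {
  cat(sprintf("deg_table: %d records, %d clusters, dialect=%s\n",
              nrow(x), length(unique(x$cluster)),
              attr(x, "source_dialect")))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  invisible(x)
}

# ---- CellRanger dialect ----------------------------------------------------

# Header pattern of the CellRanger (<= v3) per-cluster differential expression
# CSV: two leading gene columns, then a (mean counts, log2 fold change,
# adjusted p value) triplet per cluster.
.cr_patterns <- c(
  mean = "^cluster[ _](.+?)[ _]mean[ _]counts$",
  lfc  = "^cluster[ _](.+?)[ _]log2[ _]fold[ _]change$",
  padj = "^cluster[ _](.+?)[ _]adjusted[ _]p[ _]value$"
)

#' Read a CellRanger differential-expression CSV
#'
#' Expects the CellRanger "differential expression" dialect: first two columns
#' gene id and gene name, then per-cluster column triplets
#' `Cluster <k> Mean Counts`, `Cluster <k> Log2 fold change`,
#' `Cluster <k> Adjusted p value`. The adjusted p-value is used as the filter
#' p-value downstream (it is the only p-value CellRanger emits).
#'
#' @param path path to the CSV file.
#' @return a [deg_table()] with `source_dialect = "cellranger"`.
#' @export
read_cellranger_diffexp <- function(path) {
  if (!file.exists(path)) stop("read_cellranger_diffexp: no such file: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!nrow(raw) || ncol(raw) < 5) {
    stop("read_cellranger_diffexp: empty or truncated input: ", path)
  }
  hdr <- tolower(trimws(names(raw)))
  found <- lapply(.cr_patterns, function(p) {
    hit <- grepl(p, hdr)
    stats::setNames(which(hit), sub(p, "\\1", hdr[hit]))
  })
  clusters <- sort(unique(unlist(lapply(found, names))))
  if (!length(clusters)) {
    stop("read_cellranger_diffexp: malformed header, no per-cluster columns; ",
         "first offending column: ", names(raw)[3])
  }
  for (cl in clusters) {
    for (part in names(found)) {
      if (!cl %in% names(found[[part]])) {
        miss <- c(mean = "Mean Counts", lfc = "Log2 fold change",
                  padj = "Adjusted p value")[[part]]
        stop(sprintf(
          "read_cellranger_diffexp: malformed header, cluster %s lacks a '%s' column",
          cl, miss))
      }
    }
  }
  recs <- lapply(clusters, function(cl) {
    data.frame(
      gene = raw[[2L]],
      cluster = cl,
      lfc = as.numeric(raw[[found$lfc[[cl]]]]),
      pvalue = as.numeric(raw[[found$padj[[cl]]]]),
      mean_expr = as.numeric(raw[[found$mean[[cl]]]]),
      stringsAsFactors = FALSE
    )
  })
  all <- do.call(rbind, recs)
  deg_table(all$gene, all$cluster, all$lfc, all$pvalue, all$mean_expr,
            dialect = "cellranger")
}

#' Write a DEG table in the CellRanger differential-expression dialect
#'
#' The CellRanger format is a dense gene x cluster grid; (gene, cluster) pairs
#' absent from `table` are filled with LFC 0 and p-value 1 (inert under any
#' admissible filter).
#'
#' @param table a [deg_table()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_cellranger_diffexp <- function(table, path) {
  genes <- unique(table$gene)
  clusters <- sort(unique(table$cluster))
  out <- data.frame(`Feature ID` = genes, `Feature Name` = genes,
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (cl in clusters) {
    sub <- table[table$cluster == cl, , drop = FALSE]
    i <- match(genes, sub$gene)
    me <- sub$mean_expr[i]
    me[is.na(me)] <- 0
    lfc <- ifelse(is.na(i), 0, sub$lfc[i])
    p <- ifelse(is.na(i), 1, sub$pvalue[i])
    out[[sprintf("Cluster %s Mean Counts", cl)]] <- me
    out[[sprintf("Cluster %s Log2 fold change", cl)]] <- lfc
    out[[sprintf("Cluster %s Adjusted p value", cl)]] <- p
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- Seurat dialect --------------------------------------------------------

#' Read a Seurat FindAllMarkers CSV
#'
#' Accepts the long format written by `Seurat::FindAllMarkers`: columns
#' `p_val`, `avg_log2FC` (or the older `avg_logFC`), `cluster`, `gene`, and
#' optionally `p_val_adj`, which is preferred over the raw p-value when
#' present.
#'
#' @param path path to the CSV file.
#' @return a [deg_table()] with `source_dialect = "seurat"`.
#' @export
read_seurat_markers <- function(path) {
  if (!file.exists(path)) stop("read_seurat_markers: no such file: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  nm <- tolower(names(raw))
  pick <- function(cands) {
    i <- match(cands, nm)
    i <- i[!is.na(i)]
    if (length(i)) i[[1L]] else NA_integer_
  }
  gi <- pick("gene"); ci <- pick("cluster")
  if (is.na(gi) || is.na(ci)) {
    stop("read_seurat_markers: missing required column: ",
         if (is.na(gi)) "gene" else "cluster")
  }
  li <- pick(c("avg_log2fc", "avg_logfc"))
  pi_adj <- pick("p_val_adj"); pi_raw <- pick("p_val")
  if (is.na(li)) stop("read_seurat_markers: missing avg_log2FC/avg_logFC column")
  if (is.na(pi_adj) && is.na(pi_raw)) {
    stop("read_seurat_markers: missing p_val/p_val_adj column")
  }
  pi <- if (!is.na(pi_adj)) pi_adj else pi_raw
  if (!nrow(raw)) {
    warning("read_seurat_markers: file has a header but no rows: ", path)
    return(deg_table(character(), character(), numeric(), numeric(),
                     dialect = "seurat"))
  }
  mi <- pick(c("mean_expr", "avg_expr"))
  deg_table(raw[[gi]], raw[[ci]], as.numeric(raw[[li]]), as.numeric(raw[[pi]]),
            if (!is.na(mi)) as.numeric(raw[[mi]]) else NA_real_,
            dialect = "seurat")
}

#' Write a DEG table in the Seurat FindAllMarkers dialect
#'
#' @param table a [deg_table()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_seurat_markers <- function(table, path) {
  out <- data.frame(
    p_val = table$pvalue,
    avg_log2FC = table$lfc,
    cluster = table$cluster,
    gene = table$gene,
    p_val_adj = table$pvalue,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- delimited helpers -----------------------------------------------------

sniff_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) && grepl("\t", first[1])) "\t"
  else if (grepl("\\.csv$", path, ignore.case = TRUE)) ","
  else if (length(first) && grepl(",", first[1])) ","
  else "\t"
}

# tokens that mark a header row rather than data in two-column marker files
.header_tokens <- c("gene", "genes", "marker", "markers", "gene_symbol",
                    "symbol", "marker_gene", "genesymbol")

split_fields <- function(lines, delim) strsplit(lines, delim, fixed = TRUE)

# ---- user marker database --------------------------------------------------

#' Read a user-defined marker database
#'
#' Two-column delimited text (tab or comma, autodetected): cell type in the
#' first column, one marker gene per row in the second. Repeated
#' (cell type, gene) pairs accumulate evidence counts. A header row is
#' skipped automatically when its second field is a header token rather than
#' a plausible gene symbol.
#'
#' @param path path to the file.
#' @param delim optional explicit field delimiter overriding autodetection.
#' @param name database label, default "user".
#' @param weight database weight used when merging scores, default 1.
#' @return a [marker_db()].
#' @export
read_user_marker_db <- function(path, delim = NULL, name = "user", weight = 1) {
  if (!file.exists(path)) stop("read_user_marker_db: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("read_user_marker_db: user database must be non-empty: ", path)
  delim <- sniff_delim(path, delim)
  fields <- split_fields(lines, delim)
  nf <- lengths(fields)
  bad <- which(nf != 2L)
  if (length(bad)) {
    stop(sprintf("read_user_marker_db: line %d has %d fields, expected 2",
                 bad[1], nf[bad[1]]))
  }
  m <- do.call(rbind, fields)
  if (tolower(trimws(m[1, 2])) %in% .header_tokens) {
    m <- m[-1, , drop = FALSE]
    if (!nrow(m)) stop("read_user_marker_db: user database must be non-empty: ", path)
  }
  marker_db(
    entries = data.frame(cell_type = trimws(m[, 1]),
                         gene = m[, 2],
                         count = 1L,
                         stringsAsFactors = FALSE),
    name = name, weight = weight
  )
}

# ---- gene -> term map ------------------------------------------------------

#' Read a flattened gene-to-term map
#'
#' Two-column (gene, term) or three-column (gene, term, term name) delimited
#' text. Gene symbols are normalized; duplicate pairs collapse to sets.
#'
#' @param path path to the file.
#' @param delim optional explicit delimiter.
#' @return a `term_map`: list with `mapping` (term -> character vector of
#'   genes), `genes` (gene -> character vector of terms) and `term_names`.
#' @export
read_term_map <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("read_term_map: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("read_term_map: empty term map: ", path)
  delim <- sniff_delim(path, delim)
  fields <- split_fields(lines, delim)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop(sprintf("read_term_map: line %d has fewer than 2 fields", which(nf < 2L)[1]))
  }
  gene <- normalize_gene(vapply(fields, `[[`, "", 1L))
  term <- trimws(vapply(fields, `[[`, "", 2L))
  nm3 <- vapply(fields, function(f) if (length(f) >= 3L) trimws(f[[3L]]) else NA_character_, "")
  if (gene[1] == "GENE" || tolower(term[1]) %in% c("term", "go", "go_id")) {
    gene <- gene[-1]; term <- term[-1]; nm3 <- nm3[-1]
  }
  term_map(gene, term, nm3)
}

#' Construct a term map from vectors
#'
#' @param gene,term parallel vectors of gene symbols and term identifiers.
#' @param term_name optional parallel vector of human-readable term names.
#' @return a `term_map` object.
#' @export
term_map <- function(gene, term, term_name = NULL) {
  gene <- normalize_gene(gene)
  term <- trimws(as.character(term))
  keep <- nzchar(gene) & nzchar(term)
  gene <- gene[keep]; term <- term[keep]
  mapping <- lapply(split(gene, term), unique)
  genes <- lapply(split(term, gene), unique)
  names_tab <- character()
  if (!is.null(term_name)) {
    term_name <- as.character(term_name)[keep]
    ok <- !is.na(term_name) & nzchar(term_name)
    names_tab <- term_name[ok][!duplicated(term[ok])]
    names(names_tab) <- term[ok][!duplicated(term[ok])]
  }
  structure(list(mapping = mapping, genes = genes, term_names = names_tab),
            class = "term_map")
}

#' @export
print.term_map <- function(x, ...) {
  cat(sprintf("term_map: %d terms, %d genes\n",
              length(x$mapping), length(x$genes)))
  invisible(x)
}

# ---- annotation output -----------------------------------------------------

#' Write annotation results to a TSV
#'
#' Columns: cluster, rank, cell_type, uniform_score, status. Rows are ordered
#' by cluster label (ascending) then rank, so two runs on the same inputs are
#' byte-identical. Scores are printed with six decimal places.
#'
#' @param results a list of annotation results as returned by [annotate()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_annotation <- function(results, path) {
  if (!length(results)) stop("write_annotation: no results to write")
  rows <- lapply(results, function(r) {
    if (nrow(r$ranking)) {
      data.frame(cluster = r$cluster,
                 rank = seq_len(nrow(r$ranking)),
                 cell_type = r$ranking$cell_type,
                 uniform_score = sprintf("%.6f", r$ranking$score),
                 status = r$status,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(cluster = r$cluster, rank = 1L, cell_type = NA_character_,
                 uniform_score = "NA", status = r$status,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$cluster, out$rank), , drop = FALSE]
  con <- file(path, open = "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an annotation TSV written by [write_annotation()]
#'
#' @param path path to the TSV.
#' @return a data.frame with the written columns.
#' @export
read_annotation <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(cluster = "character"))
}
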