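# ---- DEG filtering ---------------------------------------------------------

#' Filter one cluster's DEGs on fold change and p-value
#'
#' Keeps records of `cluster` with `lfc >= lfc_min` and `pvalue <= p_max`,
#' preserving input order. Defaults correspond to the standard profile
#' (LFC >= 1, P <= 0.05); for PBMC-style 10x runs a stricter `lfc_min = 1.5`
#' is conventional, and the t-test DEG path pairs with `p_max = 0.001`.
#'
#' @param table a [deg_table()].
#' @param cluster cluster label to select.
#' @param lfc_min minimum log2 fold change, must be > 0.
#' @param p_max maximum p-value, in (0, 1].
#' @return data.frame of surviving records (possibly 0 rows).
#' @export
filter_degs <- function(table, cluster, lfc_min = 1, p_max = 0.05) {
  if (!is.numeric(lfc_min) || lfc_min <= 0) {
    stop("filter_degs: lfc_min must be > 0")
  }
  if (!is.numeric(p_max) || p_max <= 0 || p_max > 1) {
    stop("filter_degs: p_max must lie in (0, 1]")
  }
  cluster <- normalize_cluster(cluster)
  if (!cluster %in% table$cluster) {
    stop("filter_degs: unknown cluster label: ", cluster)
  }
  sub <- table[table$cluster == cluster, , drop = FALSE]
  out <- sub[sub$lfc >= lfc_min & sub$pvalue <= p_max, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

# ---- E vector --------------------------------------------------------------

#' Per-gene expression weight vector E
#'
#' For a cluster's filtered DEGs, each gene's weight is its absolute log2
#' fold change scaled by the mean absolute fold change of the whole filtered
#' list: `e_j = |LFC_j| * mean(|LFC|)`. The cluster-constant factor cancels
#' under z-scoring, so it only affects raw scores.
#'
#' @param filtered data.frame from [filter_degs()], non-empty.
#' @return named numeric vector of weights, one per gene.
#' @export
gene_weight_vector <- function(filtered) {
  if (!is.data.frame(filtered) || !nrow(filtered)) {
    stop("gene_weight_vector: filtered DEG list is empty")
  }
  alfc <- abs(filtered$lfc)
  e <- alfc * mean(alfc)
  names(e) <- filtered$gene
  e
}

# ---- raw scores ------------------------------------------------------------

#' Raw per-cell-type scores S = (M x E) * L
#'
#' For each candidate cell type i, the raw score is the evidence-weighted sum
#' of its markers' expression weights, scaled by the cell type's style factor:
#' `s_i = (sum_j M[i,j] e_j) * l_i`. `E` is restricted to the matrix columns
#' by gene name before the product.
#'
#' @param M evidence matrix ([build_evidence_matrix()]).
#' @param E named gene weight vector ([gene_weight_vector()]).
#' @param L style vector ([style_vector()]), aligned with `rownames(M)`.
#' @return a `score_vector` at stage "raw": named numeric over cell types.
#' @export
raw_scores <- function(M, E, L) {
  if (!nrow(M)) stop("raw_scores: empty evidence matrix")
  if (!all(colnames(M) %in% names(E))) {
    stop("raw_scores: evidence matrix columns missing from gene weight vector")
  }
  if (length(L) != nrow(M) || !identical(names(L), rownames(M))) {
    stop("raw_scores: style vector misaligned with evidence matrix rows")
  }
  e <- E[colnames(M)]
  s <- as.numeric(M %*% e) * as.numeric(L)
  score_vector(stats::setNames(s, rownames(M)), stage = "raw")
}

# ---- score vector container ------------------------------------------------

#' Construct a score vector
#'
#' A named numeric vector over candidate cell types, tagged with its pipeline
#' stage ("raw", "normalized", "harmonized", "uniform") and a degeneracy flag
#' set when z-scoring had no spread to standardize.
#'
#' @param values named numeric vector.
#' @param stage pipeline stage tag.
#' @param degenerate logical degeneracy flag.
#' @return a `score_vector`.
#' @export
score_vector <- function(values, stage = c("raw", "normalized", "harmonized",
                                           "uniform"),
                         degenerate = FALSE) {
  stage <- match.arg(stage)
  stopifnot(is.numeric(values), !is.null(names(values)))
  structure(values, stage = stage, degenerate = degenerate,
            class = c("score_vector", "numeric"))
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("score_vector [%s]%s\n", attr(x, "stage"),
              if (isTRUE(attr(x, "degenerate"))) " (degenerate)" else ""))
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

# ---- z-score normalization -------------------------------------------------

#' Z-score a raw score vector
#'
#' Centers and scales across candidate cell types using the sample standard
#' deviation (denominator p - 1). Vectors of length 1, or with zero variance,
#' cannot be standardized: every entry becomes 0 and the degenerate flag is
#' set, which later demotes the cluster's status to "ambiguous".
#'
#' @param S a raw-stage `score_vector`.
#' @return a normalized-stage `score_vector`.
#' @export
zscore_normalize <- function(S) {
  stopifnot(inherits(S, "score_vector"))
  v <- as.numeric(S)
  p <- length(v)
  d <- if (p >= 2) stats::sd(v) else 0
  if (p < 2 || !is.finite(d) || d == 0) {
    return(score_vector(stats::setNames(rep(0, p), names(S)),
                        stage = "normalized", degenerate = TRUE))
  }
  score_vector(stats::setNames((v - mean(v)) / d, names(S)),
               stage = "normalized")
}

# ---- harmonization ---------------------------------------------------------

#' Harmonize normalized score vectors onto the cell-type union
#'
#' Different databases nominate different candidate sets, so their normalized
#' vectors have different lengths. The shared axis is the lexicographically
#' sorted union of all cell-type labels; cell types missing from a database
#' are zero-filled (a z-score of 0 is that database's "no signal").
#'
#' @param vectors list of normalized-stage `score_vector`s (empty elements,
#'   i.e. length-0 vectors, are allowed and zero-fill completely).
#' @return list of harmonized-stage `score_vector`s over one common axis.
#' @export
harmonize_scores <- function(vectors) {
  stopifnot(is.list(vectors), length(vectors) >= 1)
  labels <- sort(unique(unlist(lapply(vectors, names))))
  if (!length(labels)) stop("harmonize_scores: all inputs are empty")
  lapply(vectors, function(v) {
    out <- stats::setNames(rep(0, length(labels)), labels)
    if (length(v)) out[names(v)] <- as.numeric(v)
    score_vector(out, stage = "harmonized",
                 degenerate = isTRUE(attr(v, "degenerate")))
  })
}

# ---- weighted combination --------------------------------------------------

#' Database weight specification
#'
#' Per-database merge coefficients `w` plus a scalar bias `b` for the final
#' combination `S' = sum_l w_l Z'_l + b`.
#'
#' @param weights numeric vector of non-negative weights, one per database.
#' @param bias scalar intercept, default 0.
#' @return a `weight_spec`.
#' @export
weight_spec <- function(weights, bias = 0) {
  weights <- as.numeric(weights)
  if (!length(weights) || any(is.na(weights)) || any(weights < 0)) {
    stop("weight_spec: weights must be non-negative numbers")
  }
  if (all(weights == 0)) stop("weight_spec: at least one weight must be > 0")
  structure(list(weights = weights, bias = as.numeric(bias)),
            class = "weight_spec")
}

#' Merge harmonized score vectors into the uniform score
#'
#' @param harmonized list of harmonized-stage `score_vector`s sharing one
#'   cell-type axis.
#' @param spec a [weight_spec()] with one weight per vector.
#' @return a uniform-stage `score_vector`; its degenerate flag is the OR of
#'   the inputs' flags (restricted to databases with weight > 0).
#' @export
combine_scores <- function(harmonized, spec) {
  stopifnot(is.list(harmonized), inherits(spec, "weight_spec"))
  k <- length(harmonized)
  if (length(spec$weights) != k) {
    stop(sprintf("combine_scores: %d weights for %d databases",
                 length(spec$weights), k))
  }
  axis <- names(harmonized[[1]])
  for (v in harmonized) {
    if (!identical(names(v), axis)) {
      stop("combine_scores: harmonized vectors do not share one axis")
    }
  }
  acc <- rep(0, length(axis))
  degen <- FALSE
  for (l in seq_len(k)) {
    acc <- acc + spec$weights[l] * as.numeric(harmonized[[l]])
    if (spec$weights[l] > 0 && isTRUE(attr(harmonized[[l]], "degenerate"))) {
      degen <- TRUE
    }
  }
  score_vector(stats::setNames(acc + spec$bias, axis), stage = "uniform",
               degenerate = degen)
}

# ---- ranking ---------------------------------------------------------------

#' Rank candidate cell types from a uniform score vector
#'
#' Orders cell types by score (descending), name (ascending) for ties, and
#' reports the top `top_n`. The confidence call compares top and runner-up on
#' a shifted-positive scale (minimum score mapped to 0.001, since ratios of
#' signed z-scores are meaningless): "confident" when the ratio reaches
#' `ambiguity_ratio` or only one candidate exists, else "ambiguous". A
#' degenerate uniform vector is always at most "ambiguous".
#'
#' @param uniform a uniform-stage `score_vector`, non-empty.
#' @param cluster cluster label carried into the result.
#' @param top_n number of candidates to report, default 5.
#' @param ambiguity_ratio confidence ratio threshold, default 2.
#' @return an `annotation_result`: list(cluster, ranking, status, top_n).
#' @export
rank_annotations <- function(uniform, cluster = NA_character_, top_n = 5,
                             ambiguity_ratio = 2) {
  stopifnot(inherits(uniform, "score_vector"), top_n >= 1)
  if (!length(uniform)) {
    stop("rank_annotations: empty score vector; route cluster to GO fallback")
  }
  nm <- names(uniform)
  sc <- as.numeric(uniform)
  o <- order(-sc, nm)
  nm <- nm[o]; sc <- sc[o]
  if (length(sc) == 1L) {
    status <- "confident"
  } else {
    shifted <- sc - min(sc) + 0.001
    status <- if (shifted[1] / shifted[2] >= ambiguity_ratio) "confident" else "ambiguous"
  }
  if (isTRUE(attr(uniform, "degenerate")) && status == "confident") {
    status <- "ambiguous"
  }
  keep <- seq_len(min(top_n, length(sc)))
  structure(
    list(cluster = normalize_cluster(cluster),
         ranking = data.frame(cell_type = nm[keep], score = sc[keep],
                              stringsAsFactors = FALSE),
         status = status,
         top_n = as.integer(top_n)),
    class = "annotation_result"
  )
}

#' @export
print.annotation_result <- function(x, ...) {
  cat(sprintf("cluster %s [%s]\n", x$cluster, x$status))
  if (nrow(x$ranking)) {
    for (i in seq_len(nrow(x$ranking))) {
      cat(sprintf("  %d. %-30s %10.4f\n", i, x$ranking$cell_type[i],
                  x$ranking$score[i]))
    }
  } else cat("  (no marker evidence)\n")
  invisible(x)
}

# ---- t-test DEG computation ------------------------------------------------

#' Compute per-cluster DEGs from an expression matrix by Student's t-test
#'
#' For every cluster and every gene, performs a two-sample, two-sided,
#' equal-variance (pooled) Student's t-test of the cluster's cells against
#' all other cells, and computes `LFC = log2((mean_in + eps)/(mean_out +
#' eps))` with pseudocount `eps = 1` guarding against log of zero. All genes
#' are returned; filtering happens downstream via [filter_degs()] (the
#' conventional thresholds for this path are P < 0.001, LFC >= 1).
#'
#' @param expr numeric matrix, genes x cells, with rownames.
#' @param labels per-cell cluster labels (length `ncol(expr)`).
#' @param eps pseudocount on the expression scale, default 1.
#' @return a [deg_table()] (dialect "generic") with one record per
#'   gene x cluster; clusters with fewer than 2 cells are skipped with a
#'   warning.
#' @export
compute_degs <- function(expr, labels, eps = 1) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)),
            length(labels) == ncol(expr))
  labels <- normalize_cluster(labels)
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("compute_degs: need at least 2 clusters")
  res <- list()
  for (cl in clusters) {
    inset <- labels == cl
    n1 <- sum(inset); n2 <- sum(!inset)
    if (n1 < 2 || n2 < 2) {
      warning("compute_degs: cluster ", cl, " has < 2 cells on one side; skipped")
      next
    }
    x <- expr[, inset, drop = FALSE]
    y <- expr[, !inset, drop = FALSE]
    m1 <- rowMeans(x); m2 <- rowMeans(y)
    v1 <- rowSums((x - m1)^2) / (n1 - 1)
    v2 <- rowSums((y - m2)^2) / (n2 - 1)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tstat <- (m1 - m2) / se
    p <- 2 * stats::pt(-abs(tstat), df = n1 + n2 - 2)
    # zero pooled variance: identical constants give p = 1, separated
    # constants are infinitely significant
    p[se == 0] <- ifelse(m1[se == 0] == m2[se == 0], 1, 0)
    lfc <- log2((m1 + eps) / (m2 + eps))
    res[[cl]] <- data.frame(gene = rownames(expr), cluster = cl, lfc = lfc,
                            pvalue = p, mean_expr = m1,
                            stringsAsFactors = FALSE)
  }
  if (!length(res)) stop("compute_degs: no cluster had enough cells")
  all <- do.call(rbind, res)
  deg_table(all$gene, all$cluster, all$lfc, all$pvalue, all$mean_expr,
            dialect = "generic")
}

# ---- full annotation pipeline ----------------------------------------------

#' Annotate every cluster of a DEG table against marker databases
#'
#' Per cluster: filter DEGs, build the gene weight vector E, then for each
#' database the evidence matrix M, style vector L and raw scores S; z-score
#' each database's scores across its candidates, harmonize all vectors onto
#' the cell-type union, merge them with the database weights, and rank.
#' Clusters whose filtered DEGs match no database get status "unresolved"
#' (empty ranking) and should be routed to the GO enrichment fallback.
#'
#' @param table a [deg_table()].
#' @param dbs a single [marker_db()] or list of them.
#' @param spec optional [weight_spec()]; defaults to each database's own
#'   weight and bias 0.
#' @param lfc_min,p_max DEG filter thresholds (see [filter_degs()]).
#' @param top_n,ambiguity_ratio ranking parameters (see [rank_annotations()]).
#' @return list of `annotation_result`, one per cluster, in sorted cluster
#'   label order.
#' @export
annotate <- function(table, dbs, spec = NULL, lfc_min = 1, p_max = 0.05,
                     top_n = 5, ambiguity_ratio = 2) {
  if (inherits(dbs, "marker_db")) dbs <- list(dbs)
  stopifnot(length(dbs) >= 1, all(vapply(dbs, inherits, TRUE, "marker_db")))
  if (is.null(spec)) {
    spec <- weight_spec(vapply(dbs, `[[`, numeric(1), "weight"), bias = 0)
  }
  stopifnot(inherits(spec, "weight_spec"))
  if (length(spec$weights) != length(dbs)) {
    stop("annotate: weight_spec length does not match number of databases")
  }
  clusters <- sort(unique(table$cluster))
  out <- lapply(clusters, function(cl) {
    filtered <- filter_degs(table, cl, lfc_min = lfc_min, p_max = p_max)
    if (!nrow(filtered)) {
      return(unresolved_result(cl, top_n))
    }
    E <- gene_weight_vector(filtered)
    normalized <- vector("list", length(dbs))
    any_evidence <- FALSE
    for (l in seq_along(dbs)) {
      M <- build_evidence_matrix(dbs[[l]], filtered$gene)
      if (!nrow(M)) {
        normalized[[l]] <- score_vector(stats::setNames(numeric(), character()),
                                        stage = "normalized")
        next
      }
      any_evidence <- TRUE
      S <- raw_scores(M, E, style_vector(M))
      normalized[[l]] <- zscore_normalize(S)
    }
    if (!any_evidence) return(unresolved_result(cl, top_n))
    harmonized <- harmonize_scores(normalized)
    uniform <- combine_scores(harmonized, spec)
    rank_annotations(uniform, cluster = cl, top_n = top_n,
                     ambiguity_ratio = ambiguity_ratio)
  })
  names(out) <- clusters
  out
}

unresolved_result <- function(cluster, top_n) {
  structure(
    list(cluster = normalize_cluster(cluster),
         ranking = data.frame(cell_type = character(), score = numeric(),
                              stringsAsFactors = FALSE),
         status = "unresolved",
         top_n = as.integer(top_n)),
    class = "annotation_result"
  )
}
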