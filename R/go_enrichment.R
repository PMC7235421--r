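# ---- contingency tables ----------------------------------------------------

#' Build per-term contingency tables for enrichment testing
#'
#' Foreground genes are the query cluster's DEGs; background genes are the
#' DEGs of all other clusters. Genes appearing in both sets are removed from
#' the background (shared DEGs would double-count), and the testable universe
#' is restricted to genes present in the term map (unannotated genes are
#' uninformative). One table is emitted per term with at least one foreground
#' gene: a = foreground in term, b = foreground not in term, c = background
#' in term, d = background not in term.
#'
#' @param fg character vector of foreground genes.
#' @param bg character vector of background genes.
#' @param terms a [term_map()].
#' @return data.frame with columns term, a, b, c, d.
#' @export
build_contingency_tables <- function(fg, bg, terms) {
  stopifnot(inherits(terms, "term_map"))
  fg <- unique(normalize_gene(fg))
  bg <- setdiff(unique(normalize_gene(bg)), fg)
  universe <- names(terms$genes)
  fg <- intersect(fg, universe)
  bg <- intersect(bg, universe)
  if (!length(fg)) {
    stop("build_contingency_tables: no foreground gene is annotated in the term map")
  }
  rows <- lapply(sort(names(terms$mapping)), function(tm) {
    members <- terms$mapping[[tm]]
    a <- sum(fg %in% members)
    if (a == 0L) return(NULL)
    c_ <- sum(bg %in% members)
    data.frame(term = tm, a = a, b = length(fg) - a, c = c_,
               d = length(bg) - c_, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    return(data.frame(term = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# ---- Fisher's exact (one-sided enrichment) ---------------------------------

#' One-sided Fisher's exact p-value for enrichment
#'
#' Upper-tail hypergeometric probability P(X >= a) with
#' X ~ Hypergeom(N = a+b+c+d, K = a+c, n = a+b): the chance of drawing at
#' least `a` in-term genes when sampling the foreground from the universe.
#' One-sided because depletion of a term is not evidence for a cell
#' function.
#'
#' @param a,b,c,d contingency cell counts (vectorized).
#' @return numeric p-value(s) in \[0, 1\].
#' @export
fisher_exact_greater <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("fisher_exact_greater: negative cell count")
  stats::phyper(a - 1, m = a + c, n = b + d, k = a + b, lower.tail = FALSE)
}

# ---- Benjamini-Hochberg ----------------------------------------------------

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_{j >= i} (m * p_(j) / j)`, clipped at 1, returned in the
#' original input order.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (!length(p)) return(numeric())
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("bh_adjust: p-values must lie in [0, 1]")
  }
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(m / (m:1) * p[o]))
  q[order(o)]
}

# ---- enrichment driver -----------------------------------------------------

#' GO-term enrichment of a cluster's DEGs
#'
#' Composes [build_contingency_tables()], [fisher_exact_greater()] and
#' [bh_adjust()], keeps terms with adjusted p <= `q_max`, and sorts by
#' adjusted p then term identifier. The fold enrichment
#' `(a/(a+b)) / (c/(c+d))` is `Inf` when the term is absent from the
#' background and `NA` when the background is empty.
#'
#' @param fg,bg,terms as in [build_contingency_tables()].
#' @param q_max adjusted-p cutoff, default 0.05.
#' @return data.frame with columns term, term_name, a, b, c, d, fold,
#'   pvalue, qvalue.
#' @export
enrich_terms <- function(fg, bg, terms, q_max = 0.05) {
  tab <- build_contingency_tables(fg, bg, terms)
  empty <- data.frame(term = character(), term_name = character(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), fold = numeric(), pvalue = numeric(),
                      qvalue = numeric(), stringsAsFactors = FALSE)
  if (!nrow(tab)) return(empty)
  tab$pvalue <- fisher_exact_greater(tab$a, tab$b, tab$c, tab$d)
  tab$qvalue <- bh_adjust(tab$pvalue)
  fg_rate <- tab$a / (tab$a + tab$b)
  bg_rate <- tab$c / (tab$c + tab$d)
  tab$fold <- ifelse(tab$c + tab$d == 0, NA_real_, fg_rate / bg_rate)
  tn <- terms$term_names[tab$term]
  tab$term_name <- ifelse(is.na(tn), "", tn)
  tab <- tab[tab$qvalue <= q_max, , drop = FALSE]
  tab <- tab[order(tab$qvalue, tab$term), , drop = FALSE]
  rownames(tab) <- NULL
  tab[, c("term", "term_name", "a", "b", "c", "d", "fold", "pvalue", "qvalue")]
}

#' Write enrichment results as a TSV
#'
#' Columns: cluster (when supplied), term, term_name, fg_in, fg_total,
#' bg_in, bg_total, fold, pvalue, qvalue.
#'
#' @param results data.frame from [enrich_terms()], or a named list of them
#'   (names become the cluster column).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_enrichment <- function(results, path) {
  if (is.data.frame(results)) results <- list(results)
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    if (!nrow(r)) return(NULL)
    data.frame(cluster = if (!is.null(names(results))) names(results)[i] else NA,
               term = r$term, term_name = r$term_name,
               fg_in = r$a, fg_total = r$a + r$b,
               bg_in = r$c, bg_total = r$c + r$d,
               fold = r$fold, pvalue = r$pvalue, qvalue = r$qvalue,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = character(), term = character(),
               term_name = character(), fg_in = integer(),
               fg_total = integer(), bg_in = integer(), bg_total = integer(),
               fold = numeric(), pvalue = numeric(), qvalue = numeric())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
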