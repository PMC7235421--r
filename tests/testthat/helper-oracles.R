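# Independent oracles, written as plain loops so they share no code path with
# the package implementation.

# Brute-force uniform score S' = (Z'_1..Z'_k)W + b for one cluster.
# degs: data.frame(gene, lfc, pvalue) already restricted to one cluster.
# dbs: list of data.frames (cell_type, gene, count), weights: numeric, bias.
oracle_uniform_scores <- function(degs, dbs, weights, bias = 0,
                                  lfc_min = 1, p_max = 0.05) {
  keep <- degs$lfc >= lfc_min & degs$pvalue <= p_max
  degs <- degs[keep, , drop = FALSE]
  if (!nrow(degs)) return(NULL)
  m_lfc <- mean(abs(degs$lfc))
  e <- abs(degs$lfc) * m_lfc
  names(e) <- degs$gene

  per_db <- list()
  for (db in dbs) {
    types <- unique(db$cell_type[db$gene %in% degs$gene])
    if (!length(types)) { per_db[[length(per_db) + 1L]] <- numeric(); next }
    s <- numeric(length(types)); names(s) <- types
    for (ct in types) {
      vals <- c(); tot <- 0
      for (g in degs$gene) {
        hit <- db$count[db$cell_type == ct & db$gene == g]
        if (length(hit)) {
          a <- sum(hit)
          w <- log2(a) + 0.05
          vals <- c(vals, w)
          tot <- tot + w * e[[g]]
        }
      }
      n <- length(vals)
      sdf <- if (n == 1) 1 else sqrt(sum((vals - mean(vals))^2) / n)
      s[[ct]] <- tot * (sdf * n)
    }
    p <- length(s)
    d <- if (p >= 2) sqrt(sum((s - mean(s))^2) / (p - 1)) else 0
    z <- if (p < 2 || d == 0) rep(0, p) else (s - mean(s)) / d
    names(z) <- types
    per_db[[length(per_db) + 1L]] <- z
  }
  axis <- sort(unique(unlist(lapply(per_db, names))))
  if (!length(axis)) return(NULL)
  out <- setNames(rep(bias, length(axis)), axis)
  for (l in seq_along(per_db)) {
    for (ct in names(per_db[[l]])) {
      out[[ct]] <- out[[ct]] + weights[l] * per_db[[l]][[ct]]
    }
  }
  out
}

# Naive BH: q_(i) = min_{j>=i} m p_(j)/j via an explicit double loop.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * ps[j] / j)
    q[i] <- min(1, best)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Enumeration oracle for the one-sided Fisher p: sum hypergeometric point
# probabilities (from lchoose) over all tables at least as enriched.
oracle_fisher_greater <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + c; n <- a + b
  lo <- max(0, n - (N - K)); hi <- min(n, K)
  support <- lo:hi
  lp <- lchoose(K, support) + lchoose(N - K, n - support) - lchoose(N, n)
  sum(exp(lp[support >= a]))
}

# Random small scoring instance for the oracle-equivalence suite.
random_instance <- function() {
  n_types <- sample(2:5, 1)
  n_genes <- sample(2:8, 1)
  genes <- sprintf("G%02d", seq_len(n_genes))
  types <- sprintf("T%d", seq_len(n_types))
  k <- sample(1:2, 1)
  dbs <- lapply(seq_len(k), function(z) {
    n_entries <- sample(2:12, 1)
    data.frame(cell_type = sample(types, n_entries, replace = TRUE),
               gene = sample(c(genes, sprintf("X%02d", 1:4)), n_entries,
                             replace = TRUE),
               count = sample(1:10, n_entries, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  degs <- data.frame(gene = genes,
                     lfc = round(runif(n_genes, 0.2, 4), 3),
                     pvalue = round(runif(n_genes, 0, 0.1), 4),
                     stringsAsFactors = FALSE)
  list(degs = degs, dbs = dbs,
       weights = round(runif(k, 0.2, 2), 2),
       bias = round(runif(1, -1, 1), 2))
}
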