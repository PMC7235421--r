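test_that("filter_degs matches a brute-force threshold scan", {
  tab <- deg_table(c("G1", "G2", "G3"), "1", c(1.2, 0.5, 2.0),
                   c(0.01, 0.01, 0.2))
  out <- filter_degs(tab, "1", 1, 0.05)
  expect_equal(out$gene, "G1")
  # identity when everything passes
  tab2 <- deg_table(c("A", "B"), "x", c(2, 3), c(0.001, 0.002))
  expect_equal(filter_degs(tab2, "x")$gene, c("A", "B"))
  expect_error(filter_degs(tab, "1", lfc_min = 0), "lfc_min")
  expect_error(filter_degs(tab, "1", p_max = 0), "p_max")
  expect_error(filter_degs(tab, "nope"), "unknown cluster")

  # randomized brute-force comparison, both threshold profiles
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    df <- data.frame(gene = sprintf("R%03d", seq_len(n)),
                     lfc = runif(n, -2, 4), pvalue = runif(n))
    t3 <- deg_table(df$gene, "c", df$lfc, df$pvalue)
    for (thr in list(c(1, 0.05), c(1.5, 0.05))) {
      got <- filter_degs(t3, "c", thr[1], thr[2])$gene
      want <- df$gene[df$lfc >= thr[1] & df$pvalue <= thr[2]]
      expect_identical(got, want)
    }
  }
})

test_that("gene weight vector is |LFC| times mean |LFC|", {
  f <- data.frame(gene = c("A", "B", "C"), lfc = c(1, -2, 3),
                  pvalue = rep(0.01, 3))
  expect_equal(unname(gene_weight_vector(f)), c(2, 4, 6))
  f1 <- data.frame(gene = "A", lfc = 1.7, pvalue = 0.01)
  expect_equal(unname(gene_weight_vector(f1)), 1.7^2)
  fc <- data.frame(gene = c("A", "B"), lfc = c(2.5, 2.5), pvalue = c(0.01, 0.01))
  expect_equal(unname(gene_weight_vector(fc)), c(6.25, 6.25))
  expect_error(gene_weight_vector(f[0, ]), "empty")
})

test_that("raw_scores composes M, E and L as s = (M e) * l", {
  M <- matrix(0.05, 1, 1, dimnames = list("T", "G1"))
  E <- c(G1 = 2, G2 = 9)
  L <- c(T = 1)
  expect_equal(as.numeric(raw_scores(M, E, L)), 0.1)
  # L = 0 annihilates; doubling E doubles S
  M2 <- rbind(A = c(1.05, 2.05), B = c(0, 3.05))
  colnames(M2) <- c("G1", "G2")
  L2 <- style_vector(M2)
  s1 <- as.numeric(raw_scores(M2, E, L2))
  s2 <- as.numeric(raw_scores(M2, 2 * E, L2))
  expect_equal(s2, 2 * s1)
  expect_equal(as.numeric(raw_scores(M2, E, setNames(c(0, 0), c("A", "B")))),
               c(0, 0))
  expect_error(raw_scores(M, c(G9 = 1), L), "missing")
  expect_error(raw_scores(M, E, c(X = 1)), "misaligned")
})

test_that("z-score normalization centers, scales, and flags degeneracy", {
  z <- zscore_normalize(score_vector(c(a = 1, b = 2, c = 3), "raw"))
  expect_equal(as.numeric(z), c(-1, 0, 1))
  expect_false(attr(z, "degenerate"))

  zc <- zscore_normalize(score_vector(c(a = 4, b = 4), "raw"))
  expect_equal(as.numeric(zc), c(0, 0))
  expect_true(attr(zc, "degenerate"))
  z1 <- zscore_normalize(score_vector(c(solo = 7), "raw"))
  expect_true(attr(z1, "degenerate"))

  set.seed(3)
  for (i in 1:25) {
    v <- rnorm(sample(2:20, 1), sd = runif(1, 0.1, 10))
    names(v) <- paste0("t", seq_along(v))
    z <- zscore_normalize(score_vector(v, "raw"))
    if (!attr(z, "degenerate")) {
      expect_lt(abs(mean(z)), 1e-9)
      expect_lt(abs(sd(z) - 1), 1e-9)
    }
  }
})

test_that("harmonization zero-fills over the sorted cell-type union", {
  v1 <- score_vector(c(A = 1.0), "normalized")
  v2 <- score_vector(c(B = -0.5), "normalized")
  h <- harmonize_scores(list(v1, v2))
  expect_equal(names(h[[1]]), c("A", "B"))
  expect_equal(as.numeric(h[[1]]), c(1, 0))
  expect_equal(as.numeric(h[[2]]), c(0, -0.5))
  # identical sets: values unchanged, order canonicalized
  v3 <- score_vector(c(B = 2, A = 1), "normalized")
  h3 <- harmonize_scores(list(v3))
  expect_equal(as.numeric(h3[[1]]), c(1, 2))
  # union size is the set union
  set.seed(5)
  for (i in 1:10) {
    sets <- lapply(1:3, function(j)
      sample(LETTERS[1:10], sample(1:6, 1)))
    vs <- lapply(sets, function(s)
      score_vector(setNames(rnorm(length(s)), s), "normalized"))
    h <- harmonize_scores(vs)
    expect_equal(length(h[[1]]), length(unique(unlist(sets))))
  }
  expect_error(harmonize_scores(list(score_vector(setNames(numeric(),
                                                           character()),
                                                  "normalized"))), "empty")
})

test_that("combine_scores forms the weighted sum plus bias", {
  h1 <- score_vector(c(A = 1, B = 0), "harmonized")
  h2 <- score_vector(c(A = 0, B = 2), "harmonized")
  u <- combine_scores(list(h1, h2), weight_spec(c(1, 1)))
  expect_equal(as.numeric(u), c(1, 2))
  # zero weight annihilates a database
  u2 <- combine_scores(list(h1, h2), weight_spec(c(1, 0)))
  expect_equal(as.numeric(u2), c(1, 0))
  # k = 1, w = 1, b = 0 is the identity merge
  u3 <- combine_scores(list(h1), weight_spec(1))
  expect_equal(as.numeric(u3), as.numeric(h1))
  ub <- combine_scores(list(h1), weight_spec(1, bias = 0.5))
  expect_equal(as.numeric(ub), c(1.5, 0.5))
  expect_error(combine_scores(list(h1, h2), weight_spec(1)), "2 databases")
  expect_error(weight_spec(c(0, 0)), "at least one")
  expect_error(weight_spec(-1), "non-negative")
})

test_that("ranking orders, tie-breaks, truncates, and calls confidence", {
  u <- score_vector(c(B = 1, A = 3), "uniform")
  r <- rank_annotations(u, "c", ambiguity_ratio = 2)
  expect_equal(r$ranking$cell_type, c("A", "B"))
  expect_equal(r$status, "confident")  # (3.001)/(1.001 - 1 + ... ) shifted
  tie <- rank_annotations(score_vector(c(B = 2, A = 2), "uniform"), "c")
  expect_equal(tie$ranking$cell_type[1], "A")
  expect_equal(tie$status, "ambiguous")
  many <- score_vector(setNames(3:1, c("x", "y", "z")), "uniform")
  expect_equal(nrow(rank_annotations(many, "c", top_n = 5)$ranking), 3L)
  solo <- rank_annotations(score_vector(c(only = -2), "uniform"), "c")
  expect_equal(solo$status, "confident")
  degen <- score_vector(c(A = 1, B = 0), "uniform", degenerate = TRUE)
  expect_equal(rank_annotations(degen, "c")$status, "ambiguous")
  expect_error(rank_annotations(score_vector(setNames(numeric(), character()),
                                             "uniform")), "fallback")
})

test_that("compute_degs matches stats::t.test and the stated LFC formula", {
  # planted 3v3 toy: pooled t from first principles
  x <- c(5, 6, 7); y <- c(1, 2, 3)
  sp2 <- (var(x) * 2 + var(y) * 2) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 3))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)

  expr <- rbind(GA = c(x, y), GB = rep(2, 6), GC = c(8, 8, 8, 0, 0, 0))
  labels <- rep(c("c1", "c2"), each = 3)
  tab <- compute_degs(expr, labels)
  ga <- tab[tab$gene == "GA" & tab$cluster == "c1", ]
  expect_equal(ga$pvalue, p_hand, tolerance = 1e-12)
  expect_equal(ga$lfc, log2((6 + 1) / (2 + 1)), tolerance = 1e-12)
  # cross-check against stats::t.test (the library oracle)
  expect_equal(ga$pvalue, t.test(x, y, var.equal = TRUE)$p.value,
               tolerance = 1e-12)
  # gene expressed only in c1: LFC = log2(9/1)
  gc <- tab[tab$gene == "GC" & tab$cluster == "c1", ]
  expect_equal(gc$lfc, log2(9), tolerance = 1e-12)
  # identical constant: p = 1, LFC = 0
  gb <- tab[tab$gene == "GB" & tab$cluster == "c1", ]
  expect_equal(gb$pvalue, 1)
  expect_equal(gb$lfc, 0)
  # undersized cluster is skipped with a warning
  expect_warning(
    compute_degs(expr[, 1:5, drop = FALSE], c("c1", "c1", "c2", "c2", "c3")),
    "skipped")
  expect_error(compute_degs(expr, rep("c1", 6)), "at least 2 clusters")
})

test_that("compute_degs recovers planted markers through the full pipeline", {
  spec <- fixture_spec(n_cell_types = 3, markers_per_type = 4, seed = 21)
  gen <- generate_marker_db(spec)
  truth <- setNames(names(gen$markers), as.character(1:3))
  sim <- generate_expression(gen, truth, spec, effect_size = 3, noise_sd = 0.5)
  tab <- compute_degs(sim$expr, sim$labels)
  res <- annotate(tab, gen$db, lfc_min = 1, p_max = 0.001)
  for (cl in names(truth)) {
    expect_equal(res[[cl]]$ranking$cell_type[1], truth[[cl]])
  }
})

test_that("annotate recovers planted truth and handles edge paths", {
  db <- tcell_db()
  tab <- deg_table(c("CD3D", "CD3E", "IL7R", "ZZZ1", "ZZZ2"),
                   c("1", "1", "1", "2", "2"),
                   c(2, 3, 1.5, 2, 2), rep(1e-4, 5))
  res <- annotate(tab, db)
  expect_equal(res[["1"]]$ranking$cell_type[1], "T cell")
  expect_equal(res[["2"]]$status, "unresolved")
  expect_equal(nrow(res[["2"]]$ranking), 0L)
  # second database with zero weight changes nothing
  db2 <- make_db(data.frame(cell_type = "Weird", gene = "CD3E", count = 9L),
                 name = "other")
  res2 <- annotate(tab, list(db, db2), spec = weight_spec(c(1, 0)))
  expect_equal(res2[["1"]]$ranking$cell_type[1], "T cell")
  got <- res2[["1"]]$ranking
  expect_equal(got$score[got$cell_type %in% res[["1"]]$ranking$cell_type],
               res[["1"]]$ranking$score)
})

test_that("staged pipeline equals the brute-force oracle on random instances", {
  set.seed(2024)
  for (i in 1:40) {
    inst <- random_instance()
    want <- oracle_uniform_scores(inst$degs, inst$dbs, inst$weights, inst$bias)
    got <- pipeline_uniform(inst$degs, inst$dbs, inst$weights, inst$bias)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_named_equal(got, want)
    }
  }
})

test_that("rankings are invariant to permutations and |LFC| rescaling", {
  set.seed(77)
  for (i in 1:12) {
    inst <- random_instance()
    base <- pipeline_uniform(inst$degs, inst$dbs, inst$weights, inst$bias)
    if (is.null(base)) next
    base_order <- names(sort(-base))
    # permute genes
    perm <- inst$degs[sample(nrow(inst$degs)), ]
    expect_equal(names(sort(-pipeline_uniform(perm, inst$dbs, inst$weights,
                                              inst$bias))), base_order)
    # permute databases with matching weights
    if (length(inst$dbs) == 2) {
      expect_equal(names(sort(-pipeline_uniform(inst$degs, rev(inst$dbs),
                                                rev(inst$weights),
                                                inst$bias))), base_order)
    }
    # rescale |LFC| by a positive constant (z-scoring removes the scale)
    sc <- inst$degs; sc$lfc <- sc$lfc * 3.7
    rescored <- pipeline_uniform(sc, inst$dbs, inst$weights, inst$bias,
                                 lfc_min = 1e-12)
    base_all <- pipeline_uniform(inst$degs, inst$dbs, inst$weights, inst$bias,
                                 lfc_min = 1e-12)
    expect_equal(names(sort(-rescored)), names(sort(-base_all)))
  }
})

test_that("raising one marker gene's LFC never lowers its cell type's raw score", {
  db <- tcell_db()
  scores_at <- function(lfc1) {
    f <- data.frame(gene = c("CD3D", "CD3E", "IL7R"),
                    lfc = c(lfc1, 2, 1.5), pvalue = rep(0.01, 3))
    M <- build_evidence_matrix(db, f$gene)
    as.numeric(raw_scores(M, gene_weight_vector(f), style_vector(M)))
  }
  s <- vapply(seq(1, 5, by = 0.5), scores_at, numeric(1))
  expect_true(all(diff(s) >= 0))
})
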