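test_that("PCA reproduces a dense eigendecomposition and variance accounting", {
  # rank-1 input: all cells on a line in gene space
  em <- toy_em(outer(runif(6) + 0.5, seq(0.1, 1, length.out = 5)),
               scale_tag = "log")
  emb <- run_pca(em, em$gene_ids, n_pcs = 2)
  expect_equal(emb$var_frac[1], 1, tolerance = 1e-10)

  # 4 cells x 3 genes toy vs an independent eigendecomposition oracle
  set.seed(3)
  em2 <- toy_em(matrix(runif(12, 0, 4), 3, 4), scale_tag = "log")
  emb2 <- run_pca(em2, em2$gene_ids, n_pcs = 3)
  xs <- scale(t(em2$values))
  eg <- eigen(stats::cov(xs))
  oracle <- xs %*% eg$vectors
  for (j in 1:3) {
    agree <- min(sum(abs(emb2$coords[, j] - oracle[, j])),
                 sum(abs(emb2$coords[, j] + oracle[, j])))
    expect_lt(agree, 1e-8)
  }
  # variance fractions: non-increasing, reproduce the scaled total variance
  ev <- emb2$var_frac
  expect_true(all(diff(ev) <= 1e-12))
  expect_equal(sum(ev), 1)

  expect_error(run_pca(em2, em2$gene_ids, n_pcs = 10), "exceeds available rank")
  expect_error(run_pca(em2, c("g1", "nope"), n_pcs = 2), "absent from matrix")
})

test_that("robust-z outlier flagging finds exactly the planted outlier", {
  set.seed(4)
  co <- matrix(rnorm(200), 100, 2)
  co[7, 1] <- 20 * 1.4826 * mad(co[, 1], constant = 1) + median(co[, 1])
  emb <- structure(list(coords = `rownames<-`(co, paste0("c", 1:100)),
                        var_frac = c(0.6, 0.4)), class = "Embedding")
  fl <- flag_outliers(emb, z_max = 5)
  expect_identical(names(which(fl)), "c7")
  expect_false(any(flag_outliers(emb, z_max = Inf)))
  # degenerate geometry: identical cells -> zero MAD components are skipped
  emb0 <- structure(list(coords = matrix(1, 10, 2,
                                         dimnames = list(paste0("c", 1:10), NULL))),
                    class = "Embedding")
  suppressWarnings(expect_warning(fl0 <- flag_outliers(emb0, 5), "zero MAD"))
  expect_false(any(fl0))
})

test_that("Louvain over the KNN graph recovers a planted two-blob partition", {
  em <- two_blob_em(n = 15)
  emb <- run_pca(em, em$gene_ids, n_pcs = 5)
  # k = blob size - 1: each blob is a clique of its own cells, so the
  # planted partition is the modularity optimum across the whole sweep
  # (the graph is disconnected by construction, hence the warning)
  expect_warning(sweep <- cluster_louvain_sweep(emb, k = 14, seed = 0),
                 "disconnected")
  for (a in sweep) {
    expect_equal(attr(a, "K"), 2)
    # blob memberships exactly recovered (labels are size-ordered)
    expect_equal(length(unique(a[1:15])), 1)
    expect_equal(length(unique(a[16:30])), 1)
  }
  # determinism under the same seed
  sweep2 <- suppressWarnings(cluster_louvain_sweep(emb, k = 14, seed = 0))
  expect_identical(sweep, sweep2)
})

test_that("a complete graph over identical points yields one community", {
  em <- toy_em(matrix(1, 10, 5), scale_tag = "log")
  emb <- structure(list(coords = matrix(0, 5, 3,
                                        dimnames = list(em$cell_ids, NULL))),
                   class = "Embedding")
  sweep <- cluster_louvain_sweep(emb, k = 10, resolutions = 1, seed = 0)
  expect_equal(attr(sweep[[1]], "K"), 1)
})

test_that("DEG calling matches the rank-sum oracle and its closed forms", {
  set.seed(8)
  g <- 50; n <- 60
  x <- matrix(abs(rnorm(g * n, 2, 0.5)), g, n)
  x[5, 1:30] <- x[5, 1:30] * 4            # planted 4-fold shift
  em <- toy_em(log1p(x), scale_tag = "log")
  a <- relabel_by_size(stats::setNames(rep(c(1L, 2L), each = 30), em$cell_ids))
  degs <- identify_degs(em, a)
  expect_true(any(degs$deg & degs$gene == "g5" & degs$direction == "up"))
  # p-values agree with stats::wilcox.test (normal approximation, corrected)
  for (gene in c("g5", "g1", "g20")) {
    for (k in 1:2) {
      in_g <- as.integer(a) == k
      o <- suppressWarnings(stats::wilcox.test(
        em$values[gene, in_g], em$values[gene, !in_g],
        exact = FALSE, correct = TRUE))
      p_pkg <- degs$p[degs$gene == gene & degs$cluster == k]
      expect_equal(p_pkg, o$p.value, tolerance = 1e-10)
    }
  }
  # q >= p and direction matches the fold-change sign
  expect_true(all(degs$q >= degs$p - 1e-15))
  expect_true(all((degs$direction == "up") == (degs$log2fc >= 0)))
  # a gene exactly doubled on the expression scale has log2FC = 1
  x2 <- x; x2[7, 1:30] <- 0
  em2 <- toy_em(log1p(x2), scale_tag = "log")
  em2$values[7, 1:30] <- log1p(2 * expm1(em2$values[7, 31:60]))
  d2 <- identify_degs(em2, a)
  expect_equal(d2$log2fc[d2$gene == "g7" & d2$cluster == 1], 1,
               tolerance = 1e-12)
})

test_that("permuted labels yield no DEGs (null calibration)", {
  set.seed(21)
  g <- 300; n <- 60
  x <- matrix(abs(rnorm(g * n, 2, 0.5)), g, n)
  em <- toy_em(x, scale_tag = "log")
  a <- relabel_by_size(stats::setNames(sample(rep(c(1L, 2L), each = 30)),
                                       em$cell_ids))
  degs <- identify_degs(em, a)
  expect_equal(sum(degs$deg), 0)
})

test_that("few-DEG merging folds a planted over-split and respects bounds", {
  em <- two_blob_em(n = 15)
  emb <- run_pca(em, em$gene_ids, n_pcs = 5)
  # true 2-blob labels, blob 2 randomly split in half -> 3 clusters
  set.seed(5)
  lab <- rep(c(1L, 2L), each = 15)
  lab[sample(16:30, 7)] <- 3L
  a <- relabel_by_size(stats::setNames(lab, em$cell_ids))
  m <- suppressWarnings(merge_few_deg_clusters(em, a, emb, min_up_degs = 5))
  expect_equal(attr(m$assignment, "K"), 2)
  # the halves were reunited, not shuffled
  expect_equal(length(unique(m$assignment[1:15])), 1)
  expect_equal(length(unique(m$assignment[16:30])), 1)
  expect_equal(length(attr(m$assignment, "history")), 1)

  # min_up_degs = 0 is the identity
  m0 <- merge_few_deg_clusters(em, a, emb, min_up_degs = 0)
  expect_identical(as.integer(m0$assignment), as.integer(a))

  # all clusters passing is the identity
  a2 <- relabel_by_size(stats::setNames(rep(c(1L, 2L), each = 15), em$cell_ids))
  m2 <- merge_few_deg_clusters(em, a2, emb, min_up_degs = 5)
  expect_identical(as.integer(m2$assignment), as.integer(a2))
})

test_that("tSNE embedding honours its contract", {
  skip_if_not_installed("Rtsne")
  d <- tiny_data()
  lm <- log_transform(filter_expressed_genes(d$sc, "sc"))
  emb <- run_pca(lm, select_hvgs(lm, 150), n_pcs = 10)
  y1 <- embed_2d(emb, perplexity = 10, seed = 1)
  expect_equal(dim(y1), c(nrow(emb$coords), 2))
  y2 <- embed_2d(emb, perplexity = 10, seed = 1)
  expect_identical(y1, y2)
  expect_error(embed_2d(emb, perplexity = 1000), "too large")
})
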