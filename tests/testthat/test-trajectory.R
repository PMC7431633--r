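mk_embedding <- function(coords) {
  structure(list(coords = coords,
                 var_frac = rep(1 / ncol(coords), ncol(coords))),
            class = "Embedding")
}

mk_assignment <- function(labels, cells) {
  structure(stats::setNames(as.integer(labels), cells),
            K = length(unique(labels)), resolution = NA_real_,
            class = "ClusterAssignment")
}

test_that("two clusters give a single forced lineage", {
  set.seed(1)
  co <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
              matrix(rnorm(20, 5, 0.1), 10, 2))
  rownames(co) <- paste0("c", 1:20)
  a <- mk_assignment(rep(1:2, each = 10), rownames(co))
  tr <- infer_lineages(mk_embedding(co), a, root_cluster = 1)
  expect_equal(length(tr$lineages), 1)
  expect_equal(tr$lineages$L1, c(1, 2))
  expect_error(infer_lineages(mk_embedding(co), a, root_cluster = 9),
               "not present")
})

test_that("MST over collinear centroids matches brute force over all trees", {
  set.seed(2)
  centers <- cbind(c(0, 1, 2.2, 3.1), 0)
  co <- do.call(rbind, lapply(1:4, function(k)
    sweep(matrix(rnorm(16, 0, 0.05), 8, 2), 2, centers[k, ], `+`)))
  rownames(co) <- paste0("c", 1:32)
  a <- mk_assignment(rep(1:4, each = 8), rownames(co))
  tr <- infer_lineages(mk_embedding(co), a, root_cluster = 1)
  expect_equal(length(tr$lineages), 1)
  expect_equal(tr$lineages$L1, 1:4)

  # brute-force minimum spanning tree: try every 3-edge subset of the six
  # possible edges over 4 labelled nodes, keep the connected acyclic ones
  cent <- tr$centroids
  d <- as.matrix(dist(cent))
  all_edges <- t(utils::combn(4, 2))
  best <- Inf
  for (pick in utils::combn(6, 3, simplify = FALSE)) {
    e <- all_edges[pick, , drop = FALSE]
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    if (igraph::vcount(g) == 4 && igraph::is_connected(g))
      best <- min(best, sum(d[e]))
  }
  got <- sum(d[tr$edges])
  expect_equal(got, best)
})

test_that("cells on a straight line get pseudotime in coordinate order", {
  set.seed(3)
  pos <- sort(runif(30, 0, 10))
  co <- cbind(pos, 0.5 * pos)       # a line in 2-D
  rownames(co) <- paste0("c", 1:30)
  a <- mk_assignment(cut(pos, 3, labels = FALSE), rownames(co))
  emb <- mk_embedding(co)
  tr <- infer_lineages(emb, a, root_cluster = 1)
  pt <- fit_pseudotime(emb, a, tr, weight_cutoff = 0.6, n_dims = 2)
  one <- pt[pt$lineage == "L1", ]
  expect_identical(one$cell, rownames(co))
  expect_false(is.unsorted(one$pseudotime))
  # single lineage: every cell retained at full weight
  expect_true(all(one$weight == 1))
  expect_true(all(one$retained))
  # the root cluster's cells concentrate near time zero
  expect_lt(max(one$pseudotime[a[one$cell] == 1]),
            min(one$pseudotime[a[one$cell] == 3]))
})

test_that("trunk cells split weight equally and fall below the 0.6 cutoff", {
  set.seed(4)
  # symmetric Y: trunk cluster 1 at origin, leaves 2 and 3 mirrored
  # leaves must be farther from each other than from the root, or the MST
  # degenerates into a path
  co <- rbind(matrix(rnorm(30, 0, 0.08), 15, 2),
              sweep(matrix(rnorm(20, 0, 0.08), 10, 2), 2, c(3, 2), `+`),
              sweep(matrix(rnorm(20, 0, 0.08), 10, 2), 2, c(3, -2), `+`))
  rownames(co) <- paste0("c", 1:35)
  a <- mk_assignment(rep(1:3, c(15, 10, 10)), rownames(co))
  emb <- mk_embedding(co)
  tr <- infer_lineages(emb, a, root_cluster = 1)
  expect_equal(length(tr$lineages), 2)
  pt <- suppressWarnings(fit_pseudotime(emb, a, tr, weight_cutoff = 0.6,
                                        n_dims = 2))
  trunk <- pt[pt$cell %in% paste0("c", 1:15), ]
  sums <- tapply(trunk$weight, trunk$cell, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # by symmetry neither lineage dominates the trunk in aggregate
  expect_lt(abs(mean(trunk$weight[trunk$lineage == "L1"]) - 0.5), 0.15)
  # leaf cells belong to one lineage only -> weight 1, retained
  leaf <- pt[pt$cell == "c20", ]
  expect_equal(nrow(leaf), 1)
  expect_equal(leaf$weight, 1)
})

test_that("pseudotime is invariant to rigid rotation of the embedding", {
  set.seed(5)
  pos <- sort(runif(24, 0, 8))
  co <- cbind(pos, 0.3 * pos + rnorm(24, 0, 0.02))
  rownames(co) <- paste0("c", 1:24)
  a <- mk_assignment(cut(pos, 2, labels = FALSE), rownames(co))
  theta <- 0.7
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  co_rot <- co %*% R
  rownames(co_rot) <- rownames(co)
  pt1 <- fit_pseudotime(mk_embedding(co), a,
                        infer_lineages(mk_embedding(co), a, 1), n_dims = 2)
  pt2 <- fit_pseudotime(mk_embedding(co_rot), a,
                        infer_lineages(mk_embedding(co_rot), a, 1), n_dims = 2)
  expect_equal(pt1$pseudotime, pt2$pseudotime, tolerance = 1e-8)
})

test_that("tiny lineages error and stability report behave at the margins", {
  set.seed(6)
  co <- rbind(matrix(rnorm(4, 0, 0.1), 2, 2),
              sweep(matrix(rnorm(2, 0, 0.1), 1, 2), 2, c(5, 0), `+`))
  rownames(co) <- paste0("c", 1:3)
  a <- mk_assignment(c(1, 1, 2), rownames(co))
  tr <- infer_lineages(mk_embedding(co), a, 1)
  expect_error(fit_pseudotime(mk_embedding(co), a, tr, n_dims = 2),
               "fewer than 4 cells")

  # single panel: trivially stable; runs end to end on synthetic data
  d <- tiny_data()
  lm <- suppressMessages(log_transform(filter_expressed_genes(d$sc, "sc")))
  rep1 <- suppressWarnings(suppressMessages(
    check_panel_stability(lm, panel_sizes = 150,
                          config = tiny_config(root_cluster = 1))))
  expect_true(rep1$stable)
  expect_equal(length(rep1$lineages), 1)
})

test_that("lineage paths are stable across HVG panel sizes on synthetic data", {
  d <- tiny_data()
  lm <- suppressMessages(log_transform(filter_expressed_genes(d$sc, "sc")))
  rep3 <- suppressWarnings(suppressMessages(
    check_panel_stability(lm, panel_sizes = c(150, 250, 350),
                          config = tiny_config(root_cluster = 1))))
  expect_type(rep3$stable, "logical")
  expect_equal(length(rep3$lineages), 3)
  # pure-noise data still yields a verdict without error
  set.seed(9)
  noise <- toy_em(matrix(abs(rnorm(3000, 2, 0.3)), 100, 30), scale_tag = "log")
  repn <- suppressWarnings(suppressMessages(
    check_panel_stability(noise, panel_sizes = c(40, 60),
                          config = tiny_config(n_pcs = 10, root_cluster = 1,
                                               min_up_degs = 0))))
  expect_type(repn$stable, "logical")
})
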