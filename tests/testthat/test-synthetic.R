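test_that("presets encode the experiment's scale and branching topology", {
  cfg <- preset_config("mef175")
  expect_equal(cfg$n_cells, 175)
  expect_equal(length(cfg$cluster_proportions), 6)
  expect_equal(length(topology_lineages(cfg$lineage_topology)), 3)
  expect_equal(sum(cfg$cluster_proportions), 1)
  # two small terminal fates
  expect_equal(sum(cfg$cluster_proportions < 0.1), 2)
  expect_error(preset_config("nope"), "mef175, tiny")
})

test_that("generation is bit-identical under a fixed seed", {
  a <- generate_dataset(preset_config("tiny"), seed = 9)
  b <- generate_dataset(preset_config("tiny"), seed = 9)
  expect_identical(a$sc$values, b$sc$values)
  expect_identical(a$bulk$values, b$bulk$values)
  expect_identical(a$motif_db$ranks, b$motif_db$ranks)
  expect_identical(a$truth, b$truth)
  c <- generate_dataset(preset_config("tiny"), seed = 10)
  expect_false(identical(a$sc$values, c$sc$values))
})

test_that("ground truth conserves labels, lineage cover and monotone lists", {
  d <- tiny_data()
  n <- length(d$sc$cell_ids)
  expect_equal(length(d$truth$cluster), n)
  expect_true(all(d$truth$cluster %in% 1:6))
  # every cell belongs to >= 1 lineage; trunk cells to all three
  nl <- lengths(d$truth$lineage_of)
  expect_true(all(nl >= 1))
  expect_true(all(nl[d$truth$cluster[names(nl)] %in% 1:2] == 3))
  expect_true(all(nl[d$truth$cluster[names(nl)] %in% c(4, 5, 6)] == 1))
  # pseudotime non-negative and ordered along each lineage's cluster path
  expect_true(all(d$truth$pseudotime >= 0))
  for (path in d$truth$lineages) {
    mt <- vapply(path, function(k)
      mean(d$truth$pseudotime[d$truth$cluster == k]), numeric(1))
    expect_true(all(diff(mt) > 0))
  }
  # regulon targets within the gene universe
  expect_true(all(unlist(d$truth$regulons) %in% d$sc$gene_ids))
  # monotone truth is strictly monotone on the clean bulk trajectories
  cb <- d$truth$bulk_clean
  rownames(cb) <- d$sc$gene_ids
  up <- cb[d$truth$monotone_up, , drop = FALSE]
  expect_true(all(apply(up, 1, function(x) all(diff(x) > 0))))
  down <- cb[d$truth$monotone_down, , drop = FALSE]
  expect_true(all(apply(down, 1, function(x) all(diff(x) < 0))))
  expect_length(intersect(d$truth$monotone_up, d$truth$monotone_down), 0)
})

test_that("sasp_fraction = 0 removes the SASP contrast", {
  cfg <- preset_config("tiny")
  cfg$sasp_fraction <- 0
  d <- generate_dataset(cfg, seed = 3)
  expect_false(any(d$truth$sasp_positive))
  sasp <- d$truth$program_genes$sasp
  lx <- log1p(d$sc$values[sasp, ])
  cl <- d$truth$cluster
  m_sen <- mean(lx[, cl %in% c(3, 4)])
  m_trunk <- mean(lx[, cl %in% c(1, 2)])
  expect_lt(abs(m_sen - m_trunk), 0.15)
  # and with the default fraction the contrast is present
  d2 <- tiny_data(3)
  lx2 <- log1p(d2$sc$values[d2$truth$program_genes$sasp, ])
  cl2 <- d2$truth$cluster
  expect_gt(mean(lx2[, d2$truth$sasp_positive]) -
              mean(lx2[, !d2$truth$sasp_positive & cl2 %in% c(3, 4)]), 0.2)
})

test_that("zero fraction matches the negative-binomial closed form without dropout", {
  cfg <- preset_config("tiny")
  cfg$dropout_steepness <- 0          # disables dropout by convention
  cfg$baseline_log_mean <- log(1)
  cfg$baseline_log_sd <- 0
  cfg$low_expr_fraction <- 0          # uniform mu = 1 for the closed form
  cfg$program_blocks <- lapply(cfg$program_blocks, function(b) {
    b$effect <- 0; b
  })
  cfg$tf_effect <- 0
  d <- generate_dataset(cfg, seed = 5)
  obs <- mean(d$sc$values == 0)
  size <- cfg$dispersion
  p0 <- (size / (size + 1))^size      # mu = 1 for every gene and cell
  n <- length(d$sc$values)
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(obs - p0), 3 * se + 1e-12)
})

test_that("infeasible program blocks are rejected", {
  cfg <- preset_config("tiny")
  cfg$program_blocks$cell_cycle$n <- 10000L
  expect_error(generate_dataset(cfg, seed = 1), "infeasible block sizes")
})

test_that("planted states separate in PCA space (positive silhouette of truth)", {
  skip_if_not_installed("cluster")
  d <- tiny_data()
  lm <- log_transform(filter_expressed_genes(d$sc, "sc"))
  panel <- select_hvgs(lm, 150)
  emb <- run_pca(lm, panel, n_pcs = 10)
  sil <- cluster::silhouette(as.integer(d$truth$cluster[rownames(emb$coords)]),
                             dist(emb$coords))
  expect_gt(mean(sil[, "sil_width"]), 0)
})

test_that("write_dataset emits the documented plain-text layout", {
  d <- tiny_data()
  out <- withr::local_tempdir()
  write_dataset(d, out)
  expect_true(all(file.exists(file.path(out,
    c("matrix.tsv", "matrix.mtx", "bulk.tsv", "genesets.gmt", "tfs.txt",
      "motif_ranks.tsv", "motif_annotation.tsv", "truth/cells.tsv")))))
  back <- read_expression_matrix(file.path(out, "matrix.tsv"), "tsv")
  expect_equal(back$values, d$sc$values)
  db <- read_motif_rankings(file.path(out, "motif_ranks.tsv"),
                            file.path(out, "motif_annotation.tsv"))
  expect_identical(db$ranks, d$motif_db$ranks)
})
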