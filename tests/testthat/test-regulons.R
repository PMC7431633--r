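# A controlled motif db: 25 motifs over 40 genes, with motif m_hit placing
# the module genes at the very top and every other motif uniform. (The NES of
# a single enriched motif among n motifs is bounded near (n-1)/sqrt(n), so a
# db must be comfortably larger than 10 motifs for NES >= 3 to be reachable.)
mk_db <- function(module_idx, G = 40, seed = 1) {
  set.seed(seed)
  rows <- list()
  r <- integer(G)
  r[module_idx] <- seq_along(module_idx)
  r[-module_idx] <- sample(setdiff(seq_len(G), seq_along(module_idx)))
  rows[["m_hit"]] <- r
  for (i in 1:24) rows[[paste0("m_rand", i)]] <- sample(G)
  ranks <- do.call(rbind, rows)
  colnames(ranks) <- c("TFx", paste0("g", 2:G))
  ann <- stats::setNames(rep("TFx", nrow(ranks)), rownames(ranks))
  motif_ranking_db(ranks, ann)
}

test_that("co-expression modules keep exact copies and reject noise", {
  set.seed(10)
  n <- 175
  tf <- rnorm(n, 5, 1)
  x <- rbind(TFx = tf,
             copy = tf,                      # r = 1
             anti = 10 - tf + rnorm(n, 0, .1))  # strongly negative
  noise <- matrix(rnorm(200 * n, 5, 1), 200, n)
  rownames(noise) <- paste0("n", 1:200)
  em <- expression_matrix(pmax(rbind(x, noise), 0),
                          cell_ids = paste0("c", 1:n), scale_tag = "log")
  mods <- suppressWarnings(build_coexpression_modules(em, "TFx", r_min = 0.3,
                                                      min_targets = 1))
  expect_true("copy" %in% mods$TFx)
  expect_false("anti" %in% mods$TFx)        # activating modules only
  # independent white-noise genes essentially never pass r >= 0.3 at n = 175
  expect_lt(sum(startsWith(mods$TFx, "n")), 3)

  expect_error(build_coexpression_modules(em, "absent"), "absent")
  em0 <- expression_matrix(rbind(flat = rep(1, 10), g2 = runif(10)),
                           cell_ids = paste0("c", 1:10), scale_tag = "log")
  expect_warning(m0 <- build_coexpression_modules(em0, "flat"),
                 "zero variance")
  expect_length(m0, 0)
})

test_that("motif pruning keeps planted enrichment and drops unsupported modules", {
  module <- paste0("g", 2:9)            # 8 genes, planted at ranks 1..8
  db <- mk_db(module_idx = 2:9)
  regs <- prune_modules_with_motifs(list(TFx = module), db,
                                    top_fraction = 0.25, nes_min = 3)
  expect_length(regs, 1)
  expect_setequal(regs$TFx$targets, module)
  expect_identical(regs$TFx$motifs, "m_hit")
  expect_true(all(regs$TFx$targets %in% module))  # pruning never adds genes
  expect_true("TFx" %in% regs$TFx$genes)          # include_tf default

  # NES recomputed independently from first principles
  Tw <- ceiling(0.25 * 40)
  aucs <- vapply(db$motif_ids, function(m)
    recovery_auc(db$ranks[m, module], T = Tw, set_size = length(module)),
    numeric(1))
  nes_hand <- (aucs - mean(aucs)) / sd(aucs)
  expect_equal(unname(regs$TFx$nes), unname(nes_hand["m_hit"]))
  expect_gte(nes_hand["m_hit"], 3)

  # a module uncorrelated with every ranking yields no regulon
  set.seed(33)
  rand_mod <- sample(paste0("g", 10:40), 8)
  regs0 <- prune_modules_with_motifs(list(TFx = rand_mod), db,
                                     top_fraction = 0.25, nes_min = 3)
  expect_length(regs0, 0)

  # db too small for a meaningful NES
  small <- motif_ranking_db(db$ranks[1:5, ], db$motif_to_tf[1:5])
  expect_error(prune_modules_with_motifs(list(TFx = module), small),
               "fewer than 10 motifs")
})

test_that("genes outside every significant motif window are excluded", {
  db <- mk_db(module_idx = 2:9)
  # append a module gene parked at the bottom rank of the supporting motif
  bottom_gene <- names(which(db$ranks["m_hit", ] == 40))
  module <- c(paste0("g", 2:9), bottom_gene)
  regs <- prune_modules_with_motifs(list(TFx = module), db,
                                    top_fraction = 0.25, nes_min = 3)
  expect_false(bottom_gene %in% regs$TFx$targets)
  expect_setequal(regs$TFx$targets, paste0("g", 2:9))
})

test_that("NES-based selection is invariant to motif duplication", {
  module <- paste0("g", 2:9)
  db <- mk_db(module_idx = 2:9)
  ranks2 <- rbind(db$ranks, db$ranks)
  rownames(ranks2) <- c(rownames(db$ranks), paste0(rownames(db$ranks), "_dup"))
  ann2 <- stats::setNames(rep("TFx", nrow(ranks2)), rownames(ranks2))
  db2 <- motif_ranking_db(ranks2, ann2)
  r1 <- prune_modules_with_motifs(list(TFx = module), db, 0.25, 3)
  r2 <- prune_modules_with_motifs(list(TFx = module), db2, 0.25, 3)
  expect_setequal(r2$TFx$targets, r1$TFx$targets)
  expect_setequal(r2$TFx$motifs, c("m_hit", "m_hit_dup"))
})

test_that("lineage commitment is the Pearson correlation with pseudotime", {
  n <- 100
  set.seed(12)
  tt <- sort(runif(n, 0, 4))
  cells <- paste0("c", 1:n)
  pt <- data.frame(cell = cells, lineage = "L1", pseudotime = tt,
                   dist = 0, weight = 1, retained = TRUE)
  class(pt) <- c("PseudotimeAssignment", "data.frame")
  z <- rbind(perfect = (tt - mean(tt)) / sd(tt),
             indep = rnorm(n),
             flat = rep(0, n))
  colnames(z) <- cells
  scores <- structure(list(auc = (z - min(z)) / (max(z) - min(z)), z = z,
                           rank_cutoff = 100, seed = 0),
                      class = "RecoveryScore")
  expect_warning(cm <- lineage_committed_regulons(scores, pt, "L1",
                                                  r_thresh = 0.3),
                 "constant activity")
  expect_equal(cm$r[cm$regulon == "perfect"], 1, tolerance = 1e-12)
  expect_true(cm$retained[cm$regulon == "perfect"])
  expect_equal(cm$retained[cm$regulon == "indep"],
               abs(cm$r[cm$regulon == "indep"]) > 0.3)
  expect_false("flat" %in% cm$regulon)
  # null calibration: independent activity rarely exceeds |r| = 0.3 at n = 100
  set.seed(99)
  rs <- replicate(200, cor(rnorm(n), tt))
  expect_lt(mean(abs(rs) > 0.3), 0.02)
})
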