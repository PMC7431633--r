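# Synthetic single-cell + bulk senescence data with full ground truth.
#
# The generator emulates the structure of a replicative-senescence fibroblast
# experiment: six cell states (a proliferating root 1, a transition state 2,
# two senescent states 3 and 4, and two small states 5 "duplication-regained"
# and 6 "translation-elevated") arranged on a branching topology
# 1 -> 2 -> {3 -> 4, 5, 6}, SASP genes elevated only in a scattered subset of
# cells of the senescent states, planted TF regulons co-expressed with smooth
# pseudotime programs, a motif-ranking database in which true targets sit in
# the top percentile, and a matched six-passage bulk series with monotone
# senescence genes and a planted platform offset.

# Program activation shapes: continuous piecewise-linear functions of true
# pseudotime t (cluster depth + U(0,1), so t spans [0,4) on the main path),
# gated by cluster membership, with the change concentrated in ramps of
# width 0.3 around the state boundaries (plateaus inside a state). Values
# in [0,1]. `ramp(t, b)` rises 0 -> 1 across the boundary at depth b.
.ramp <- function(t, b) pmin(1, pmax(0, (t - (b - 0.15)) / 0.3))

# Cumulative staircase: 0 before state 2, ~1/3 per crossed boundary, 1 in the
# terminal state of the main path.
.stairs <- function(t) (.ramp(t, 1) + .ramp(t, 2) + .ramp(t, 3)) / 3

.program_activation <- function(program, t, cluster, sasp_pos) {
  a <- switch(program,
    cell_cycle = {
      v <- 1 - .stairs(t)
      v[cluster == 5L] <- 0.8           # duplication-regained state
      v
    },
    senescence_core = {
      v <- .stairs(t)
      v[cluster == 6L] <- 0.25          # translation fate is not inflamed
      v
    },
    sasp = as.numeric(sasp_pos),
    transition = (.ramp(t, 1) - .ramp(t, 2)) * as.numeric(cluster %in% 1:4),
    stress_c3 = (.ramp(t, 2) - .ramp(t, 3)) * as.numeric(cluster %in% c(3L, 4L)),
    apoptosis_c4 = .ramp(t, 3) * as.numeric(cluster %in% c(3L, 4L)),
    duplication_c5 = as.numeric(cluster == 5L),
    translation = as.numeric(cluster == 6L) + 0.25 * (cluster == 1L),
    stop("unknown program: ", program)
  )
  a
}

# TF activation shapes, cycled over planted TFs. TF 1 is the senescence
# driver whose regulon must track main-lineage pseudotime; the remaining
# shapes are deliberately near-orthogonal to the pseudotime axis (fate
# indicators, a transition bump, proliferation-linked declines) so that no
# second TF rides the same monotone program.
.tf_activation <- function(idx, t, cluster, slope) {
  shape <- ((idx - 1L) %% 8L) + 1L
  switch(shape,
    slope * .stairs(t),                              # 1: senescence driver
    slope * (1 - .stairs(t)),                        # 2: proliferation-linked
    as.numeric(cluster == 5L),                       # 3: state-5 fate
    as.numeric(cluster == 6L),                       # 4: state-6 fate
    (.ramp(t, 1) - .ramp(t, 2)) * (cluster %in% 1:4), # 5: transition bump
    as.numeric(cluster == 1L),                       # 6: root program
    as.numeric(cluster %in% c(1L, 5L)),              # 7: duplication program
    as.numeric(cluster %in% c(1L, 6L))               # 8: biosynthesis program
  )
}

#' Preset generator configurations
#'
#' `"mef175"` mirrors the scale of a replicative-senescence fibroblast
#' experiment: 175 cells, 10,000 genes, six states (two small, ~7% each) on the
#' branching topology 1->2 with fates 2->3->4, 2->5 and 2->6, 30% of senescent
#' cells SASP-positive. `"tiny"` keeps the same topology at 60 cells x 500
#' genes for fast tests.
#'
#' @param name `"mef175"` or `"tiny"`
#' @return a `GeneratorConfig` list; see [generate_dataset()]
#' @export
preset_config <- function(name = c("mef175", "tiny")) {
  if (!is.character(name) || !name[[1]] %in% c("mef175", "tiny"))
    stop("unknown preset '", name[[1]], "'; available: mef175, tiny")
  name <- name[[1]]
  topo <- list(parent = c(`1` = NA, `2` = 1, `3` = 2, `4` = 3, `5` = 2, `6` = 2),
               depth  = c(`1` = 0, `2` = 1, `3` = 2, `4` = 3, `5` = 2, `6` = 2))
  base <- list(
    cluster_proportions = c(0.20, 0.24, 0.23, 0.19, 0.07, 0.07),
    lineage_topology = topo,
    senescent_clusters = c(3L, 4L),
    sasp_fraction = 0.3,
    regulon_pseudotime_slope = 1.0,
    tf_effect = 2.5,
    dropout_midpoint = 0.5,
    dropout_steepness = 2.5,
    dispersion = 60,
    baseline_log_mean = log(30),
    baseline_log_sd = 1.0,
    low_expr_fraction = 0.12,
    bulk_noise_sd = 0.1,
    bulk_platform_sd = 1.5,
    seed = 0L
  )
  if (name == "mef175") {
    cfg <- c(base, list(
      name = "mef175", n_cells = 175L, n_genes = 10000L,
      program_blocks = list(
        cell_cycle      = list(n = 400L, effect = 3.0),
        senescence_core = list(n = 300L, effect = 3.0),
        sasp            = list(n = 80L, effect = 0.8),
        transition      = list(n = 250L, effect = 2.5),
        stress_c3       = list(n = 300L, effect = 3.0),
        apoptosis_c4    = list(n = 300L, effect = 3.0),
        duplication_c5  = list(n = 200L, effect = 3.0),
        translation     = list(n = 300L, effect = 3.0)),
      n_tfs = 8L, targets_per_tf = 80L))
  } else {
    cfg <- c(base, list(
      name = "tiny", n_cells = 60L, n_genes = 500L,
      program_blocks = list(
        cell_cycle      = list(n = 60L, effect = 3.0),
        senescence_core = list(n = 45L, effect = 3.0),
        sasp            = list(n = 25L, effect = 0.8),
        transition      = list(n = 30L, effect = 2.5),
        stress_c3       = list(n = 40L, effect = 3.0),
        apoptosis_c4    = list(n = 40L, effect = 3.0),
        duplication_c5  = list(n = 30L, effect = 3.0),
        translation     = list(n = 40L, effect = 3.0)),
      n_tfs = 4L, targets_per_tf = 12L))
  }
  class(cfg) <- "GeneratorConfig"
  validate_generator_config(cfg)
  cfg
}

#' @rdname preset_config
#' @param config a `GeneratorConfig`
#' @export
validate_generator_config <- function(config) {
  p <- config$cluster_proportions
  if (abs(sum(p) - 1) > 1e-8) stop("cluster_proportions must sum to 1")
  par <- config$lineage_topology$parent
  k <- length(par)
  if (length(p) != k) stop("proportions/topology cluster count mismatch")
  if (sum(is.na(par)) != 1L) stop("lineage_topology must have exactly one root")
  if (config$sasp_fraction < 0 || config$sasp_fraction > 1)
    stop("sasp_fraction must be in [0,1]")
  for (f in c("n_cells", "n_genes", "n_tfs", "targets_per_tf"))
    if (config[[f]] <= 0) stop(f, " must be positive")
  n_planted <- sum(vapply(config$program_blocks, function(b) b$n, numeric(1))) +
    config$n_tfs * (config$targets_per_tf + 1L)
  if (n_planted > config$n_genes)
    stop("infeasible block sizes: ", n_planted, " planted genes > n_genes = ",
         config$n_genes)
  invisible(config)
}

#' Root-to-leaf cluster paths of a lineage topology
#'
#' @param topology a `lineage_topology` list with a named `parent` vector
#'   (NA marks the root)
#' @return list of integer label paths, in leaf label order
#' @export
topology_lineages <- function(topology) {
  par <- topology$parent
  labs <- as.integer(names(par))
  children <- lapply(labs, function(l) labs[!is.na(par) & par == l])
  leaves <- labs[vapply(children, length, integer(1)) == 0L]
  lapply(sort(leaves), function(leaf) {
    path <- leaf
    while (!is.na(par[[as.character(path[1])]]))
      path <- c(par[[as.character(path[1])]], path)
    as.integer(path)
  })
}

#' Generate a synthetic senescence dataset with ground truth
#'
#' Draws per-cell true pseudotimes along the configured branching topology,
#' builds log-mean expression as baseline + program loadings x piecewise-linear
#' activations, samples negative-binomial counts, applies logistic dropout
#' (probability decreasing in the mean; `dropout_steepness <= 0` disables
#' dropout), and normalizes to RPKM-like values by a median-ratio cell size
#' factor. Also emits a matched bulk passage series (main-lineage means at six
#' increasing pseudotimes, with a per-gene platform offset and lognormal
#' noise), gene sets (GMT programs), a TF list, a motif-ranking database whose
#' true targets rank in the top percentile (10% scattered genome-wide), and
#' the full ground truth.
#'
#' @param config a `GeneratorConfig` from [preset_config()]
#' @param seed integer; same seed, same config -> bit-identical outputs
#' @return list with elements `sc` (ExpressionMatrix, rpkm), `bulk`
#'   (BulkSeries, fpkm), `gene_sets`, `tfs`, `motif_db`, `truth`, `config`
#' @export
generate_dataset <- function(config, seed = config$seed) {
  validate_generator_config(config)
  with_seed(as.integer(seed), generate_dataset_impl(config))
}

generate_dataset_impl <- function(config) {
  n_cells <- config$n_cells; n_genes <- config$n_genes
  topo <- config$lineage_topology
  k <- length(topo$parent)
  labs <- as.integer(names(topo$parent))

  ## --- cells: labels, pseudotime, lineage membership, SASP flags ----------
  sizes <- apportion(n_cells, config$cluster_proportions)
  cluster <- rep(labs, sizes)
  depth <- topo$depth[as.character(cluster)]
  t_true <- depth + stats::runif(n_cells)
  cell_ids <- sprintf("cell%03d", seq_len(n_cells))

  lineages <- topology_lineages(topo)
  lin_names <- paste0("L", seq_along(lineages))
  lineage_of <- lapply(seq_len(n_cells), function(i)
    lin_names[vapply(lineages, function(p) cluster[i] %in% p, logical(1))])

  sasp_pos <- rep(FALSE, n_cells)
  sen <- cluster %in% config$senescent_clusters
  sasp_pos[sen] <- stats::runif(sum(sen)) < config$sasp_fraction

  ## --- gene universe and planted blocks -----------------------------------
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  cursor <- 0L
  take <- function(n) {
    idx <- cursor + seq_len(n); cursor <<- cursor + n
    idx
  }
  program_idx <- lapply(config$program_blocks, function(b) take(b$n))
  tf_target_idx <- lapply(seq_len(config$n_tfs), function(i)
    take(config$targets_per_tf))
  tf_idx <- take(config$n_tfs)
  tf_ids <- sprintf("TF%d", seq_len(config$n_tfs))
  gene_ids[tf_idx] <- tf_ids

  ## --- log-mean expression -------------------------------------------------
  baseline <- stats::rnorm(n_genes, config$baseline_log_mean, config$baseline_log_sd)
  # a weakly expressed background tail, so the expressed-gene filter has a
  # realistic quantile to bite on (planted genes are never in the tail)
  background <- setdiff(seq_len(n_genes),
                        c(unlist(program_idx), unlist(tf_target_idx), tf_idx))
  n_low <- min(length(background),
               floor((config$low_expr_fraction %||% 0) * n_genes))
  if (n_low > 0) {
    low_idx <- sample(background, n_low)
    baseline[low_idx] <- stats::rnorm(n_low, log(0.4), 0.5)
  }
  logmu <- matrix(rep(baseline, n_cells), n_genes, n_cells)
  act_prog <- list()
  for (p in names(program_idx)) {
    a <- .program_activation(p, t_true, cluster, sasp_pos)
    act_prog[[p]] <- a
    eff <- config$program_blocks[[p]]$effect *
      stats::runif(length(program_idx[[p]]), 0.75, 1.25)
    logmu[program_idx[[p]], ] <- logmu[program_idx[[p]], ] + outer(eff, a)
  }
  act_tf <- list()
  for (i in seq_len(config$n_tfs)) {
    a <- .tf_activation(i, t_true, cluster, config$regulon_pseudotime_slope)
    act_tf[[tf_ids[i]]] <- a
    rows <- c(tf_target_idx[[i]], tf_idx[i])
    eff <- config$tf_effect * stats::runif(length(rows), 0.75, 1.25)
    logmu[rows, ] <- logmu[rows, ] + outer(eff, a)
  }

  ## --- counts, dropout, RPKM-like normalization ---------------------------
  mu <- exp(logmu)
  counts <- matrix(stats::rnbinom(n_genes * n_cells, mu = mu,
                                  size = config$dispersion),
                   n_genes, n_cells)
  if (config$dropout_steepness > 0) {
    p_drop <- stats::plogis(-config$dropout_steepness *
                              (log(pmax(mu, 1e-12)) - config$dropout_midpoint))
    keep <- matrix(stats::runif(n_genes * n_cells), n_genes, n_cells) >= p_drop
    counts <- counts * keep
  }
  # median-of-ratios size factors (composition-robust: a cluster's program
  # load must not deflate the background genes it shares with other states)
  logref <- rowMeans(log1p(counts))
  sf <- apply(counts, 2, function(cc)
    stats::median((cc + 1) / exp(logref)))
  sf <- sf / stats::median(sf)
  rpkm <- sweep(counts, 2, sf, "/")
  sc <- expression_matrix(rpkm, gene_ids = gene_ids, cell_ids = cell_ids,
                          scale_tag = "rpkm")

  ## --- bulk passage series (main lineage, population expectation) ---------
  main <- lineages[[which.max(vapply(lineages, length, integer(1)))]]
  t_bulk <- seq(0.4, max(topo$depth[as.character(main)]) + 0.6, length.out = 6)
  passages <- paste0("PD", 5 + seq_along(t_bulk))
  bulk_cluster <- main[pmin(length(main), floor(t_bulk) + 1L)]
  bulk_logmu <- matrix(rep(baseline, length(t_bulk)), n_genes, length(t_bulk))
  for (p in names(program_idx)) {
    # population expectation: SASP is carried by a sasp_fraction subset
    a <- .program_activation(p, t_bulk, bulk_cluster,
                             sasp_pos = rep(TRUE, length(t_bulk)))
    if (p == "sasp") a <- a * config$sasp_fraction * pmin(1, pmax(0, (t_bulk - 2)))
    bulk_logmu[program_idx[[p]], ] <- bulk_logmu[program_idx[[p]], ] +
      config$program_blocks[[p]]$effect * outer(rep(1, length(program_idx[[p]])), a)
  }
  for (i in seq_len(config$n_tfs)) {
    a <- .tf_activation(i, t_bulk, bulk_cluster, config$regulon_pseudotime_slope)
    rows <- c(tf_target_idx[[i]], tf_idx[i])
    bulk_logmu[rows, ] <- bulk_logmu[rows, ] + config$tf_effect * outer(rep(1, length(rows)), a)
  }
  clean_bulk <- exp(bulk_logmu)
  platform <- stats::rnorm(n_genes, 0, config$bulk_platform_sd)
  noisy <- exp(bulk_logmu + platform +
                 matrix(stats::rnorm(n_genes * length(t_bulk), 0,
                                     config$bulk_noise_sd),
                        n_genes, length(t_bulk)))
  bulk <- bulk_series(expression_matrix(noisy, gene_ids = gene_ids,
                                        cell_ids = passages, scale_tag = "rpkm"))

  # monotone ground truth on noise-free, bulk-expressed trajectories
  expressed <- rowSums(clean_bulk > 1) == ncol(clean_bulk)
  d <- t(apply(clean_bulk, 1, diff))
  mono_up <- gene_ids[expressed & apply(d > 0, 1, all)]
  mono_down <- gene_ids[expressed & apply(d < 0, 1, all)]

  ## --- gene sets, TF list, motif DB ---------------------------------------
  gene_sets <- lapply(program_idx, function(ix) gene_ids[ix])
  regulons_truth <- stats::setNames(
    lapply(tf_target_idx, function(ix) gene_ids[ix]), tf_ids)
  motif_db <- .plant_motif_db(gene_ids, tf_ids, regulons_truth)

  truth <- list(
    cluster = stats::setNames(cluster, cell_ids),
    pseudotime = stats::setNames(t_true, cell_ids),
    lineages = stats::setNames(lineages, lin_names),
    lineage_of = stats::setNames(lineage_of, cell_ids),
    sasp_positive = stats::setNames(sasp_pos, cell_ids),
    regulons = regulons_truth,
    driver_tf = tf_ids[[1L]],
    monotone_up = mono_up,
    monotone_down = mono_down,
    program_genes = gene_sets,
    bulk_clean = clean_bulk
  )
  list(sc = sc, bulk = bulk, gene_sets = gene_sets, tfs = tf_ids,
       motif_db = motif_db, truth = truth, config = config)
}

# Plant a motif DB: per TF one true motif (90% of targets + the TF drawn
# uniformly within the top 1% of ranks, 10% scattered genome-wide) and three
# uniform decoy motifs annotated to the same TF, so pruning must separate a
# genuine ranking from same-TF noise.
.plant_motif_db <- function(gene_ids, tf_ids, regulons_truth) {
  G <- length(gene_ids)
  top <- max(ceiling(0.01 * G), max(lengths(regulons_truth)) + 2L)
  rows <- list(); ann <- character(0)
  for (tf in tf_ids) {
    targets <- match(c(regulons_truth[[tf]], tf), gene_ids)
    id <- sprintf("motif_%s", tf)
    planted <- targets[stats::runif(length(targets)) < 0.9]
    r <- integer(G)
    r[planted] <- sample(top, length(planted))
    rest <- which(r == 0L)
    r[rest] <- sample(setdiff(seq_len(G), r[planted]), length(rest))
    rows[[id]] <- r
    ann[id] <- tf
    for (m in 1:3) {
      id <- sprintf("decoy_%s_%d", tf, m)
      rows[[id]] <- sample(G)
      ann[id] <- tf
    }
  }
  ranks <- do.call(rbind, rows)
  colnames(ranks) <- gene_ids
  motif_ranking_db(ranks, ann)
}

#' Write a generated dataset to a directory of plain-text files
#'
#' Emits `matrix.tsv` (and `matrix.mtx` + id files), `bulk.tsv`,
#' `genesets.gmt`, `tfs.txt`, `motif_ranks.tsv`, `motif_annotation.tsv`, and
#' ground-truth tables under `truth/`.
#'
#' @param dataset result of [generate_dataset()]
#' @param dir output directory (created if needed)
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_matrix(dataset$sc, file.path(dir, "matrix.tsv"), "tsv")
  write_expression_matrix(dataset$sc, file.path(dir, "matrix.mtx"), "mtx")
  write_expression_matrix(dataset$bulk, file.path(dir, "bulk.tsv"), "tsv")
  write_gene_sets_gmt(dataset$gene_sets, file.path(dir, "genesets.gmt"))
  writeLines(dataset$tfs, file.path(dir, "tfs.txt"))
  write_motif_rankings(dataset$motif_db, file.path(dir, "motif_ranks.tsv"),
                       file.path(dir, "motif_annotation.tsv"))
  td <- file.path(dir, "truth")
  dir.create(td, showWarnings = FALSE)
  tr <- dataset$truth
  utils::write.table(
    data.frame(cell = names(tr$cluster), cluster = unname(tr$cluster),
               pseudotime = unname(tr$pseudotime),
               sasp_positive = unname(tr$sasp_positive)),
    file.path(td, "cells.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(tr$monotone_up, file.path(td, "monotone_up.txt"))
  writeLines(tr$monotone_down, file.path(td, "monotone_down.txt"))
  utils::write.table(
    data.frame(tf = rep(names(tr$regulons), lengths(tr$regulons)),
               target = unlist(tr$regulons, use.names = FALSE)),
    file.path(td, "regulons.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
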