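# End-to-end pipeline: orchestrates preprocess -> cluster -> score ->
# trajectory -> regulons -> bulk integration with deterministic seeding,
# structured logging and a provenance manifest.

#' Pipeline configuration
#'
#' All tunable parameters of the analysis with their conventional defaults:
#' 2,500-gene HVG panel (sweep 2,500/5,000/8,000 via
#' [check_panel_stability()]), 50 PCs, KNN k = 10, Louvain resolutions 0.8-2.0,
#' Wilcoxon DEGs at q < 0.05 and |log2FC| > 0.25, merge threshold 10
#' upregulated DEGs, recovery AUC over the top 3,000 ranks, projection-weight
#' cutoff 0.6, co-expression r >= 0.3, NES >= 3 with a top-5% motif window,
#' commitment |r| > 0.3.
#'
#' @param ... overrides of the defaults listed above
#' @return validated `PipelineConfig` list
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_detected_genes = 2000,
    hvg_size = 2500, hvg_bins = 20,
    n_pcs = 50, outlier_z = Inf,
    knn_k = 10, resolutions = seq(0.8, 2, by = 0.2),
    deg_q = 0.05, deg_lfc = 0.25, min_up_degs = 10,
    auc_top = 3000,
    mst_dims = 10, weight_cutoff = 0.6, pt_tol = 1e-3, pt_max_iter = 15,
    coexpr_r = 0.3, coexpr_min_targets = 5,
    top_fraction = 0.05, nes_min = 3,
    commitment_r = 0.3,
    root_gene_set = "cell_cycle", root_cluster = NULL,
    perplexity = 10, seed = 0)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_pipeline_config(cfg)
}

#' @rdname pipeline_config
#' @param config a `PipelineConfig`
#' @export
validate_pipeline_config <- function(config) {
  chk <- function(field, ok) if (!ok) stop("invalid config field '", field, "'")
  chk("weight_cutoff", config$weight_cutoff >= 0 && config$weight_cutoff <= 1)
  chk("deg_q", config$deg_q > 0 && config$deg_q <= 1)
  chk("coexpr_r", config$coexpr_r > 0 && config$coexpr_r < 1)
  chk("top_fraction", config$top_fraction > 0 && config$top_fraction <= 1)
  chk("commitment_r", config$commitment_r >= 0 && config$commitment_r <= 1)
  chk("hvg_size", config$hvg_size >= 1)
  chk("n_pcs", config$n_pcs >= 2)
  chk("knn_k", config$knn_k >= 1)
  chk("auc_top", config$auc_top >= 1)
  chk("resolutions", all(config$resolutions > 0))
  chk("perplexity", config$perplexity > 0)
  structure(config, class = "PipelineConfig")
}

#' Choose the trajectory root cluster
#'
#' The starting state of senescence trajectories is the proliferating
#' cluster; unless `config$root_cluster` is set explicitly, the root is the
#' cluster with the highest mean Z-normalized activity of the configured
#' proliferation gene set (`config$root_gene_set`, default `"cell_cycle"`).
#'
#' @param em ExpressionMatrix used for scoring (log scale)
#' @param assignment a `ClusterAssignment`
#' @param config a [pipeline_config()]
#' @param gene_sets named list of gene sets (used if `scores` not given)
#' @param scores optional precomputed `RecoveryScore` containing the root set
#' @return root cluster label
#' @export
pick_root <- function(em, assignment, config, gene_sets = NULL,
                      scores = NULL) {
  if (!is.null(config$root_cluster)) return(config$root_cluster)
  if (is.null(scores)) {
    if (is.null(gene_sets) || !config$root_gene_set %in% names(gene_sets))
      stop("root selection needs gene set '", config$root_gene_set, "'")
    scores <- score_gene_sets(em, gene_sets[config$root_gene_set],
                              T = config$auc_top, seed = config$seed)
  }
  z <- scores$z[config$root_gene_set, names(assignment)]
  ks <- sort(unique(as.integer(assignment)))
  mz <- vapply(ks, function(kk) mean(z[as.integer(assignment) == kk]),
               numeric(1))
  ks[which.max(mz)]
}

#' Run the full senescence-lineage pipeline
#'
#' Stages, in order: cell/gene QC and log transform; HVG selection; PCA +
#' KNN/Louvain clustering with resolution sweep and few-DEG merging; per-cell
#' gene-set scoring; lineage inference and principal-curve pseudotime rooted
#' at the proliferating cluster; regulon discovery, scoring and
#' lineage-commitment testing; pseudo-bulk/bulk integration. All stage outputs
#' are written as TSV under `outdir` together with `manifest.json` recording
#' parameters, seed and per-file checksums; a rerun with the same inputs and
#' config is bit-identical. On stage failure a `FAILED` marker naming the
#' stage is left in `outdir` and the error is rethrown.
#'
#' @param dataset list with `sc`, `bulk`, `gene_sets`, `tfs`, `motif_db` (and
#'   optionally `truth`), e.g. from [generate_dataset()] or assembled from
#'   [read_expression_matrix()] and friends
#' @param config a [pipeline_config()]
#' @param outdir output directory; `NULL` skips writing
#' @return list with all stage results (`filtered`, `logmat`, `panel`,
#'   `clustering`, `scores`, `root`, `tree`, `pseudotime`, `modules`,
#'   `regulons`, `regulon_scores`, `commitment`, `pseudobulk`, `monotone`,
#'   `overlap`, `joint_pca`, `tsne`, `manifest`)
#' @export
run_pipeline <- function(dataset, config = pipeline_config(), outdir = NULL) {
  config <- validate_pipeline_config(config)
  stage <- "init"
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    unlink(file.path(outdir, "FAILED"))
  }
  on_fail <- function(e) {
    if (!is.null(outdir))
      writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
                 file.path(outdir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    stage <- "preprocess"
    filtered <- filter_cells(dataset$sc, config$min_detected_genes)
    filtered <- filter_expressed_genes(filtered, "sc")
    logmat <- log_transform(filtered)
    panel <- select_hvgs(logmat, config$hvg_size, config$hvg_bins)

    stage <- "cluster"
    cl <- cluster_cells(logmat, panel, n_pcs = config$n_pcs, k = config$knn_k,
                        resolutions = config$resolutions,
                        min_up_degs = config$min_up_degs, q_max = config$deg_q,
                        lfc_min = config$deg_lfc, outlier_z = config$outlier_z,
                        seed = config$seed)
    logmat <- em_subset(logmat, cells = which(logmat$cell_ids %in%
                                                names(cl$assignment)))
    tsne <- if (requireNamespace("Rtsne", quietly = TRUE) &&
                config$perplexity < (nrow(cl$embedding$coords) - 1) / 3)
      embed_2d(cl$embedding, config$perplexity, config$seed) else NULL

    stage <- "aucell"
    ranks <- rank_genes_per_cell(logmat, seed = config$seed)
    scores <- score_gene_sets(logmat, dataset$gene_sets, T = config$auc_top,
                              seed = config$seed, ranks = ranks)

    stage <- "trajectory"
    root <- pick_root(logmat, cl$assignment, config, dataset$gene_sets,
                      scores = if (config$root_gene_set %in%
                                   rownames(scores$z)) scores else NULL)
    tree <- infer_lineages(cl$embedding, cl$assignment, root,
                           n_dims = config$mst_dims)
    pt <- fit_pseudotime(cl$embedding, cl$assignment, tree,
                         weight_cutoff = config$weight_cutoff,
                         tol = config$pt_tol, max_iter = config$pt_max_iter,
                         n_dims = config$mst_dims)

    stage <- "regulons"
    tfs <- intersect(dataset$tfs, logmat$gene_ids)
    modules <- build_coexpression_modules(logmat, tfs, config$coexpr_r,
                                          config$coexpr_min_targets)
    regs <- prune_modules_with_motifs(modules, dataset$motif_db,
                                      config$top_fraction, config$nes_min)
    regulon_scores <- NULL; commitment <- NULL
    if (length(regs)) {
      regulon_scores <- score_regulons(logmat, regs, T = config$auc_top,
                                       seed = config$seed, ranks = ranks)
      commitment <- do.call(rbind, lapply(names(tree$lineages), function(ln)
        lineage_committed_regulons(regulon_scores, pt, ln,
                                   config$commitment_r)))
    }

    stage <- "bulk_integration"
    pb <- pseudobulk_average(filtered, cl$assignment)
    bulk_f <- filter_expressed_genes(dataset$bulk, "bulk")
    mono <- select_monotone_genes(bulk_f)
    annot <- if (!is.null(dataset$gene_sets$senescence_core))
      dataset$gene_sets$senescence_core else character(0)
    ov <- overlap_expressed_genes(filtered$gene_ids, bulk_f$gene_ids, annot)
    shared <- intersect(filtered$gene_ids, bulk_f$gene_ids)
    jpca <- joint_pca_compare(bulk_f, em_subset(pb, genes =
                                                  which(pb$gene_ids %in% shared)),
                              shared)

    stage <- "manifest"
    result <- list(filtered = filtered, logmat = logmat, panel = panel,
                   clustering = cl, scores = scores, root = root, tree = tree,
                   pseudotime = pt, modules = modules, regulons = regs,
                   regulon_scores = regulon_scores, commitment = commitment,
                   pseudobulk = pb, monotone = mono, overlap = ov,
                   joint_pca = jpca, tsne = tsne, config = config)
    if (!is.null(outdir)) {
      write_pipeline_outputs(result, outdir)
      result$manifest <- write_manifest(config, outdir)
    }
    result
  }, error = on_fail)
}

write_tsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

write_pipeline_outputs <- function(res, outdir) {
  write_tsv(as.data.frame(res$panel), file.path(outdir, "hvg_panel.tsv"))
  emb <- data.frame(cell = rownames(res$clustering$embedding$coords),
                    res$clustering$embedding$coords, check.names = FALSE)
  write_tsv(emb, file.path(outdir, "pca_scores.tsv"))
  a <- res$clustering$assignment
  write_tsv(data.frame(cell = names(a), cluster = as.integer(a)),
            file.path(outdir, "clusters.tsv"))
  write_tsv(res$clustering$degs[res$clustering$degs$deg, ],
            file.path(outdir, "degs.tsv"))
  if (!is.null(res$tsne))
    write_tsv(data.frame(cell = rownames(res$tsne), res$tsne),
              file.path(outdir, "tsne.tsv"))
  write_tsv(data.frame(set = rownames(res$scores$auc), res$scores$auc,
                       check.names = FALSE),
            file.path(outdir, "geneset_auc.tsv"))
  write_tsv(data.frame(set = rownames(res$scores$z), res$scores$z,
                       check.names = FALSE),
            file.path(outdir, "geneset_auc_z.tsv"))
  writeLines(c(paste0("root\t", res$root),
               vapply(names(res$tree$lineages), function(nm)
                 paste0(nm, "\t", paste(res$tree$lineages[[nm]],
                                        collapse = "-")), character(1))),
             file.path(outdir, "lineages.txt"))
  write_tsv(as.data.frame(res$pseudotime), file.path(outdir, "pseudotime.tsv"))
  if (length(res$regulons)) {
    write_tsv(data.frame(
      tf = vapply(res$regulons, `[[`, "", "tf"),
      n_targets = vapply(res$regulons, function(r) length(r$targets), 0),
      max_nes = vapply(res$regulons, function(r) max(r$nes), 0),
      targets = vapply(res$regulons, function(r)
        paste(r$targets, collapse = ","), "")),
      file.path(outdir, "regulons.tsv"))
    write_tsv(res$commitment, file.path(outdir, "commitment.tsv"))
  }
  write_expression_matrix(res$pseudobulk, file.path(outdir, "pseudobulk.tsv"))
  writeLines(res$monotone$up, file.path(outdir, "monotone_up.txt"))
  writeLines(res$monotone$down, file.path(outdir, "monotone_down.txt"))
  write_tsv(data.frame(region = names(res$overlap),
                       count = as.integer(res$overlap)),
            file.path(outdir, "venn.tsv"))
  write_tsv(data.frame(column = rownames(res$joint_pca$coords),
                       type = res$joint_pca$type,
                       res$joint_pca$coords[, 1:min(5, ncol(res$joint_pca$coords))],
                       check.names = FALSE),
            file.path(outdir, "joint_pca.tsv"))
  invisible(outdir)
}

write_manifest <- function(config, outdir) {
  files <- sort(setdiff(list.files(outdir), c("manifest.json", "FAILED")))
  params <- lapply(unclass(config), function(v)
    if (is.numeric(v) && any(!is.finite(v))) as.character(v) else v)
  manifest <- list(
    package = "senlineage",
    version = as.character(utils::packageVersion("senlineage")),
    stages = c("preprocess", "cluster", "aucell", "trajectory", "regulons",
               "bulk_integration"),
    seed = config$seed,
    parameters = params,
    checksums = as.list(tools::md5sum(file.path(outdir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
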