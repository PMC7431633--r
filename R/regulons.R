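# TF co-expression modules, motif-ranking pruning into regulons, and
# lineage-committed regulon detection by pseudotime correlation.

#' TF co-expression modules
#'
#' Per transcription factor, candidate targets are the genes (excluding the TF
#' itself) whose Pearson correlation with the TF across cells is at least
#' `r_min` on log values. Only positively correlated (activating) candidates
#' are kept. TFs with zero expression variance are skipped, and TFs with fewer
#' than `min_targets` candidates are dropped, each with a warning.
#'
#' @param em log-scale ExpressionMatrix
#' @param tf_list character vector of TF gene ids present in the matrix
#' @param r_min correlation threshold in (0,1), default 0.3
#' @param min_targets minimum candidate count (default 5)
#' @return named list TF -> character vector of candidate target gene ids
#' @export
build_coexpression_modules <- function(em, tf_list, r_min = 0.3,
                                       min_targets = 5) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (r_min <= 0 || r_min >= 1) stop("r_min must be in (0,1)")
  missing <- setdiff(tf_list, em$gene_ids)
  if (length(missing)) stop("TF(s) absent from matrix: ",
                            paste(missing, collapse = ", "))
  x <- t(em$values)                      # cells x genes
  modules <- list()
  for (tf in tf_list) {
    tfx <- x[, tf]
    if (stats::sd(tfx) == 0) {
      warning("TF ", tf, " has zero variance; skipped")
      next
    }
    r <- suppressWarnings(stats::cor(x, tfx))[, 1]
    r[is.na(r)] <- 0
    cand <- setdiff(names(r)[r >= r_min], tf)
    if (length(cand) < min_targets) {
      warning("TF ", tf, " has ", length(cand), " candidate target(s) (< ",
              min_targets, "); dropped")
      next
    }
    modules[[tf]] <- cand
  }
  modules
}

#' Prune co-expression modules against motif rankings
#'
#' For each TF module and each motif in the database, the module's enrichment
#' in the motif's whole-genome ranking is the recovery-curve AUC over the top
#' `ceil(top_fraction * G)` positions (the same statistic as per-cell scoring,
#' applied to a motif ranking instead of a cell ranking). The NES of a motif
#' is the z-score of its AUC relative to the module's AUC distribution over
#' all motifs in the database. A motif supports the regulon when it is
#' annotated to the module's TF and its NES >= `nes_min`; the pruned targets
#' are the module genes ranked inside the top window of at least one
#' supporting motif. A regulon is emitted only if it has >= 1 supporting motif
#' and >= 1 target.
#'
#' @param modules named list TF -> candidate targets
#'   ([build_coexpression_modules()])
#' @param db a [motif_ranking_db()] with >= 10 motifs whose gene universe
#'   covers the module genes
#' @param top_fraction leading-edge window as a fraction of the gene universe
#'   (default 0.05)
#' @param nes_min NES threshold (default 3.0)
#' @param include_tf include the TF itself among the regulon's scored genes
#'   (default TRUE)
#' @return list of `Regulon`s: each a list (tf, targets, motifs, nes, genes)
#'   where `genes` is the scored set (targets plus TF when `include_tf`)
#' @export
prune_modules_with_motifs <- function(modules, db, top_fraction = 0.05,
                                      nes_min = 3.0, include_tf = TRUE) {
  stopifnot(inherits(db, "MotifRankingDB"))
  if (nrow(db$ranks) < 10)
    stop("motif database has fewer than 10 motifs; NES is not meaningful")
  G <- ncol(db$ranks)
  Tw <- ceiling(top_fraction * G)
  regulons <- list()
  for (tf in names(modules)) {
    genes <- modules[[tf]]
    missing <- setdiff(genes, db$gene_ids)
    if (length(missing)) stop("module gene(s) absent from motif database: ",
                              paste(utils::head(missing, 3), collapse = ", "))
    aucs <- vapply(db$motif_ids, function(m)
      recovery_auc(db$ranks[m, genes], T = Tw, set_size = length(genes)),
      numeric(1))
    s <- stats::sd(aucs)
    nes <- if (is.na(s) || s == 0) rep(0, length(aucs)) else (aucs - mean(aucs)) / s
    names(nes) <- db$motif_ids
    own <- db$motif_ids[db$motif_to_tf == tf]
    sig <- own[nes[own] >= nes_min]
    if (!length(sig)) next
    in_window <- Reduce(`|`, lapply(sig, function(m)
      db$ranks[m, genes] <= Tw))
    targets <- genes[in_window]
    if (!length(targets)) next
    regulons[[tf]] <- structure(
      list(tf = tf, targets = targets, motifs = sig, nes = nes[sig],
           include_tf = include_tf,
           genes = if (include_tf) unique(c(tf, targets)) else targets),
      class = "Regulon")
  }
  regulons
}

#' @export
print.Regulon <- function(x, ...) {
  cat(sprintf("Regulon %s: %d targets, %d supporting motif(s), max NES %.2f\n",
              x$tf, length(x$targets), length(x$motifs), max(x$nes)))
  invisible(x)
}

#' Score regulon activity per cell
#'
#' Convenience wrapper around [score_gene_sets()] for a list of regulons.
#'
#' @param em ExpressionMatrix
#' @param regulons list of `Regulon`s from [prune_modules_with_motifs()]
#' @param T rank cutoff (default 3000)
#' @param seed,ranks forwarded to [score_gene_sets()]
#' @return a `RecoveryScore` with one row per regulon (named by TF)
#' @export
score_regulons <- function(em, regulons, T = 3000, seed = 0, ranks = NULL) {
  sets <- stats::setNames(lapply(regulons, `[[`, "genes"),
                          vapply(regulons, `[[`, "", "tf"))
  score_gene_sets(em, sets, T = T, seed = seed, ranks = ranks)
}

#' Lineage-committed regulons
#'
#' Per regulon, the Pearson correlation between its Z-normalized AUC and
#' pseudotime over the cells retained on the lineage (projection weight above
#' the cutoff). A regulon is retained as lineage-committed when |r| exceeds
#' `r_thresh`. Regulons with constant AUC over the retained cells are excluded
#' with a warning.
#'
#' @param scores a `RecoveryScore` of regulon activity ([score_regulons()])
#' @param pseudotime a `PseudotimeAssignment` ([fit_pseudotime()])
#' @param lineage lineage name (e.g. `"L1"`)
#' @param r_thresh retention threshold (default 0.3)
#' @return data.frame (regulon, lineage, r, n_cells, retained)
#' @export
lineage_committed_regulons <- function(scores, pseudotime, lineage,
                                       r_thresh = 0.3) {
  stopifnot(inherits(scores, "RecoveryScore"))
  pt <- pseudotime[pseudotime$lineage == lineage & pseudotime$retained, ]
  if (!nrow(pt)) stop("no retained cells on lineage ", lineage)
  cells <- intersect(pt$cell, colnames(scores$z))
  tt <- pt$pseudotime[match(cells, pt$cell)]
  out <- list()
  for (rg in rownames(scores$z)) {
    zz <- scores$z[rg, cells]
    if (stats::sd(zz) == 0) {
      warning("regulon ", rg, " has constant activity on lineage ", lineage,
              "; excluded")
      next
    }
    r <- stats::cor(zz, tt)
    out[[rg]] <- data.frame(regulon = rg, lineage = lineage, r = r,
                            n_cells = length(cells),
                            retained = abs(r) > r_thresh,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
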