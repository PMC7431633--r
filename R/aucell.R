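# Per-cell gene-set activity by recovery-curve AUC over the top of each
# cell's expression ranking, with cross-cell Z-normalization.

#' Rank genes within each cell
#'
#' Per cell, genes are ranked 1..G by decreasing expression. Ties (ubiquitous
#' among zeros) are broken by a seeded random permutation, shared across
#' cells, so rankings are reproducible, no gene is systematically favoured,
#' and cells with identical profiles receive identical rankings.
#'
#' @param em ExpressionMatrix (any non-negative scale; AUC depends on ranks
#'   only)
#' @param seed seed for the tie-break permutation (recorded by the caller)
#' @return genes x cells integer matrix of ranks (1 = highest expression)
#' @export
rank_genes_per_cell <- function(em, seed = 0) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  x <- em$values
  G <- nrow(x)
  perm <- with_seed(derive_seed(seed, "rank"), sample.int(G))
  ranks <- matrix(0L, G, ncol(x), dimnames = dimnames(x))
  for (j in seq_len(ncol(x))) {
    ord <- order(-x[, j], perm)
    ranks[ord, j] <- seq_len(G)
  }
  ranks
}

#' Recovery-curve AUC of one gene set in one cell
#'
#' The recovery curve R(i), i = 1..T, counts how many set genes rank at or
#' above i. The raw area is the rectangle (right-endpoint) sum of R over the
#' top `T` ranks, and the AUC is that area divided by the maximum attainable
#' area (all set genes packed at the very top), so AUC is in [0,1] and
#' comparable across set sizes, reaching 1 exactly when the set occupies the
#' top ranks.
#'
#' @param set_ranks integer ranks of the set's genes in the cell's ranking
#' @param T rank cutoff (default 3000)
#' @param set_size the set's size (defaults to `length(set_ranks)`; pass
#'   explicitly when `set_ranks` was pre-filtered)
#' @return AUC in [0,1]
#' @export
recovery_auc <- function(set_ranks, T = 3000, set_size = length(set_ranks)) {
  if (T <= 0) stop("T must be >= 1")
  if (set_size < 1) stop("set_size must be >= 1")
  r <- set_ranks[set_ranks <= T]
  raw <- sum(T - r + 1)
  m <- min(set_size, T)
  max_area <- m * (m + 1) / 2 + (T - m) * m
  raw / max_area
}

#' Score gene sets per cell by recovery AUC
#'
#' Computes the recovery-curve AUC of every gene set in every cell over the
#' top `T` ranks, then Z-normalizes each set's AUC across cells
#' ((AUC - mean) / sd; a set with identical AUC in all cells gets Z = 0).
#' Sets are intersected with the gene universe; a partial intersection is
#' logged, an empty one is an error.
#'
#' @param em ExpressionMatrix
#' @param gene_sets named list of gene-id vectors (or a single vector)
#' @param T rank cutoff (default 3000, capped at the gene count)
#' @param seed tie-break seed forwarded to [rank_genes_per_cell()]
#' @param ranks optional precomputed rank matrix (genes x cells)
#' @return a `RecoveryScore`: list with `auc` and `z` (sets x cells matrices),
#'   `rank_cutoff`, `seed`
#' @export
score_gene_sets <- function(em, gene_sets, T = 3000, seed = 0, ranks = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (!is.list(gene_sets)) gene_sets <- list(set = gene_sets)
  if (is.null(names(gene_sets)))
    names(gene_sets) <- paste0("set", seq_along(gene_sets))
  T <- min(T, length(em$gene_ids))
  if (is.null(ranks)) ranks <- rank_genes_per_cell(em, seed = seed)
  auc <- matrix(NA_real_, length(gene_sets), ncol(ranks),
                dimnames = list(names(gene_sets), colnames(ranks)))
  for (s in names(gene_sets)) {
    genes <- intersect(gene_sets[[s]], em$gene_ids)
    if (!length(genes))
      stop("gene set '", s, "' has empty intersection with the gene universe")
    if (length(genes) < length(unique(gene_sets[[s]])))
      msg("set '", s, "': ", length(genes), "/",
          length(unique(gene_sets[[s]])), " genes present")
    sr <- ranks[genes, , drop = FALSE]
    m <- length(genes)
    auc[s, ] <- apply(sr, 2, recovery_auc, T = T, set_size = m)
  }
  z <- t(apply(auc, 1, function(a) {
    s <- stats::sd(a)
    if (is.na(s) || s == 0) rep(0, length(a)) else (a - mean(a)) / s
  }))
  dimnames(z) <- dimnames(auc)
  structure(list(auc = auc, z = z, rank_cutoff = T, seed = seed),
            class = "RecoveryScore")
}

#' @export
print.RecoveryScore <- function(x, ...) {
  cat(sprintf("RecoveryScore: %d sets x %d cells (top %d ranks)\n",
              nrow(x$auc), ncol(x$auc), x$rank_cutoff))
  invisible(x)
}
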