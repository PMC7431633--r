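# Cluster pseudo-bulk averaging, monotone passage-series gene selection,
# expressed-gene overlaps, joint PCA of bulk samples and pseudo-bulks.

#' Average single-cell expression per cluster
#'
#' Column `c` of the result is the arithmetic mean, on the input scale, over
#' the cells assigned to cluster `c`.
#'
#' @param em ExpressionMatrix
#' @param assignment a `ClusterAssignment` covering the matrix cells
#' @return ExpressionMatrix, genes x clusters (columns `cluster1..K`)
#' @export
pseudobulk_average <- function(em, assignment) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  cells <- names(assignment)
  if (!all(cells %in% em$cell_ids)) stop("assignment cells absent from matrix")
  ks <- sort(unique(as.integer(assignment)))
  cols <- vapply(ks, function(kk) {
    idx <- cells[as.integer(assignment) == kk]
    if (!length(idx)) stop("cluster ", kk, " is empty")
    rowMeans(em$values[, idx, drop = FALSE])
  }, numeric(length(em$gene_ids)))
  cols <- matrix(cols, nrow = length(em$gene_ids), ncol = length(ks))
  expression_matrix(cols, gene_ids = em$gene_ids,
                    cell_ids = paste0("cluster", ks),
                    scale_tag = em$scale_tag)
}

#' Consecutively monotone genes along a passage series
#'
#' A gene is upregulated when its expression strictly increases between every
#' consecutive passage pair, downregulated when it strictly decreases; all
#' other genes are unlisted. `slack` flat (not reversed) steps may be allowed
#' for sensitivity analysis (default 0 = strict).
#'
#' @param bulk a [bulk_series()] (expressed-gene bulk filter already applied)
#' @param slack number of tolerated flat steps (default 0)
#' @return a `MonotoneGeneLists`: list with `up`, `down` (gene ids) and
#'   `trajectories` (the genes x passages matrix)
#' @export
select_monotone_genes <- function(bulk, slack = 0) {
  stopifnot(inherits(bulk, "BulkSeries"))
  x <- bulk$values
  d <- x[, -1L, drop = FALSE] - x[, -ncol(x), drop = FALSE]
  up <- rowSums(d > 0) >= ncol(d) - slack & rowSums(d < 0) == 0
  down <- rowSums(d < 0) >= ncol(d) - slack & rowSums(d > 0) == 0
  structure(list(up = bulk$gene_ids[up], down = bulk$gene_ids[down],
                 trajectories = x[up | down, , drop = FALSE]),
            class = "MonotoneGeneLists")
}

#' @export
print.MonotoneGeneLists <- function(x, ...) {
  cat(sprintf("MonotoneGeneLists: %d consecutively up, %d consecutively down\n",
              length(x$up), length(x$down)))
  invisible(x)
}

#' Three-way overlap of expressed-gene collections
#'
#' Counts of all 7 Venn regions between expressed single-cell genes, expressed
#' bulk genes, and an annotation gene set (e.g. literature senescence genes).
#'
#' @param sc_expressed,bulk_expressed,annotation_set character vectors
#' @return named integer vector: `sc_only`, `bulk_only`, `annot_only`,
#'   `sc_bulk`, `sc_annot`, `bulk_annot`, `all_three`
#' @export
overlap_expressed_genes <- function(sc_expressed, bulk_expressed,
                                    annotation_set) {
  a <- unique(sc_expressed); b <- unique(bulk_expressed)
  c_ <- unique(annotation_set)
  u <- unique(c(a, b, c_))
  ia <- u %in% a; ib <- u %in% b; ic <- u %in% c_
  c(sc_only = sum(ia & !ib & !ic),
    bulk_only = sum(!ia & ib & !ic),
    annot_only = sum(!ia & !ib & ic),
    sc_bulk = sum(ia & ib & !ic),
    sc_annot = sum(ia & !ib & ic),
    bulk_annot = sum(!ia & ib & ic),
    all_three = sum(ia & ib & ic))
}

#' Joint PCA of bulk samples and cluster pseudo-bulks
#'
#' Both matrices are restricted to the shared expressed-gene set,
#' log-transformed (if not already), standardized per gene across the combined
#' columns, and decomposed by PCA with columns (samples + pseudo-bulks) as
#' observations. Column data-type labels are returned so that the first
#' component can be read as the platform (data-type) axis and later components
#' as shared biology.
#'
#' @param bulk a `BulkSeries` (linear scale)
#' @param pseudobulk genes x clusters ExpressionMatrix
#'   ([pseudobulk_average()])
#' @param genes character vector of shared expressed genes (>= 50)
#' @return list: `coords` (columns x PCs), `var_frac`, `type` (character,
#'   `"bulk"`/`"pseudobulk"` per column)
#' @export
joint_pca_compare <- function(bulk, pseudobulk, genes) {
  genes <- intersect(intersect(genes, bulk$gene_ids), pseudobulk$gene_ids)
  if (length(genes) < 50)
    stop("overlap gene set too small (", length(genes), " < 50)")
  lb <- if (bulk$scale_tag == "log") bulk$values[genes, , drop = FALSE] else
    log1p(bulk$values[genes, , drop = FALSE])
  lp <- if (pseudobulk$scale_tag == "log") pseudobulk$values[genes, , drop = FALSE] else
    log1p(pseudobulk$values[genes, , drop = FALSE])
  m <- cbind(lb, lp)
  type <- c(rep("bulk", ncol(lb)), rep("pseudobulk", ncol(lp)))
  if (ncol(m) < 3) stop("need >= 3 total columns")
  x <- t(m)
  sds <- apply(x, 2, stats::sd)
  x <- scale(x[, sds > 0, drop = FALSE])
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  list(coords = pc$x, var_frac = pc$sdev^2 / sum(pc$sdev^2),
       type = stats::setNames(type, colnames(m)))
}
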