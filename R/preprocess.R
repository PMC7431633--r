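# Cell QC, expressed-gene filters, log transform, HVG selection.

#' Remove cells with too few detected genes
#'
#' @param em ExpressionMatrix on counts or RPKM scale
#' @param min_detected_genes keep cells with at least this many nonzero genes
#' @return filtered ExpressionMatrix, survivor order preserved
#' @export
filter_cells <- function(em, min_detected_genes = 2000) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (em$scale_tag == "log") stop("filter_cells expects counts or rpkm scale")
  detected <- colSums(em$values > 0)
  keep <- detected >= min_detected_genes
  if (!any(keep)) stop("all cells removed at min_detected_genes = ",
                       min_detected_genes)
  if (any(!keep))
    msg("filter_cells: removed ", sum(!keep), " cell(s): ",
        paste(em$cell_ids[!keep], collapse = ", "))
  em_subset(em, cells = which(keep))
}

#' Keep expressed genes
#'
#' Single-cell rule: keep genes whose natural log of mean expression across
#' cells exceeds 0.01 (i.e. mean RPKM > exp(0.01)); a gene with zero mean fails
#' by definition. Bulk rule: keep genes with FPKM > 1 in every passage. The
#' realized quantile of the single-cell threshold is attached as attribute
#' `realized_quantile` (fraction of genes removed).
#'
#' @param em ExpressionMatrix (sc mode: RPKM scale) or BulkSeries (bulk mode)
#' @param mode `"sc"` or `"bulk"`
#' @param log_threshold sc-mode threshold on ln(mean) (default 0.01)
#' @param fpkm_min bulk-mode per-sample minimum (default 1)
#' @return filtered ExpressionMatrix
#' @export
filter_expressed_genes <- function(em, mode = c("sc", "bulk"),
                                   log_threshold = 0.01, fpkm_min = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (em$scale_tag == "log") stop("filter_expressed_genes expects linear scale")
  if (mode == "sc") {
    m <- rowMeans(em$values)
    keep <- m > 0 & log(pmax(m, .Machine$double.xmin)) > log_threshold
  } else {
    if (!inherits(em, "BulkSeries"))
      msg("bulk-mode filter applied to a non-BulkSeries matrix")
    keep <- rowSums(em$values > fpkm_min) == ncol(em$values)
  }
  if (!any(keep)) stop("no genes pass the ", mode, " expressed-gene filter")
  msg("filter_expressed_genes(", mode, "): kept ", sum(keep), "/", length(keep),
      " genes")
  out <- em_subset(em, genes = which(keep))
  if (inherits(em, "BulkSeries")) out <- bulk_series(out)
  attr(out, "realized_quantile") <- mean(!keep)
  out
}

#' Natural-log transform
#'
#' `x -> ln(1 + x)`; sets `scale_tag = "log"`. Applying it to an already
#' log-scale matrix is an error.
#'
#' @param em ExpressionMatrix on a linear scale
#' @return log-scale ExpressionMatrix
#' @export
log_transform <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (em$scale_tag == "log") stop("matrix is already log-transformed")
  out <- expression_matrix(log1p(em$values), scale_tag = "log")
  if (inherits(em, "BulkSeries")) out <- bulk_series(out)
  out
}

#' Select highly variable genes by binned normalized dispersion
#'
#' Per gene, mean and dispersion (= variance / mean) are computed on log-scale
#' values; genes are binned into `n_bins` equal-frequency bins by mean and the
#' dispersion is z-scored within each bin. The panel is the top `target_size`
#' genes by normalized dispersion (ties broken lexicographically by gene id
#' for determinism). A bin whose dispersion standard deviation is zero gets
#' normalized dispersion 0.
#'
#' @param em log-scale ExpressionMatrix
#' @param target_size panel size; the conventional sweep is 2500/5000/8000
#' @param n_bins number of mean-expression bins (default 20)
#' @return an `HVGPanel`: data.frame (gene, mean, dispersion, bin,
#'   norm_dispersion) sorted by normalized dispersion, with attribute
#'   `target_size`
#' @export
select_hvgs <- function(em, target_size = 2500, n_bins = 20) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (em$scale_tag != "log") stop("select_hvgs expects a log-scale matrix")
  if (target_size < 1) stop("target_size must be >= 1")
  G <- length(em$gene_ids)
  if (G < n_bins) stop("fewer genes (", G, ") than bins (", n_bins, ")")
  mu <- rowMeans(em$values)
  v <- apply(em$values, 1, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  # equal-frequency bins by mean; rank ties resolved by gene id for stability
  ord <- order(mu, em$gene_ids)
  bin <- integer(G)
  bin[ord] <- ceiling(seq_len(G) / (G / n_bins))
  nd <- numeric(G)
  for (b in unique(bin)) {
    i <- bin == b
    s <- stats::sd(disp[i])
    nd[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  sel <- order(-nd, em$gene_ids)
  n_keep <- min(target_size, G)
  panel <- data.frame(gene = em$gene_ids[sel], mean = mu[sel],
                      dispersion = disp[sel], bin = bin[sel],
                      norm_dispersion = nd[sel],
                      stringsAsFactors = FALSE)[seq_len(n_keep), ]
  rownames(panel) <- NULL
  attr(panel, "target_size") <- target_size
  class(panel) <- c("HVGPanel", "data.frame")
  panel
}
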