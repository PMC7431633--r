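# PCA, outlier flagging, KNN/Louvain clustering with resolution sweep,
# cluster-vs-rest DEG calling, few-DEG cluster merging, 2-D embedding.

#' PCA of cells over an HVG panel
#'
#' Restricts the log-scale matrix to the panel, centers and unit-scales each
#' gene (zero-variance genes dropped), and returns cell scores for the top
#' `n_pcs` components together with the variance fraction of every component
#' of the scaled matrix.
#'
#' @param em log-scale ExpressionMatrix
#' @param panel an `HVGPanel` (or character vector of gene ids)
#' @param n_pcs number of components to keep (default 50)
#' @return an `Embedding`: list with `coords` (cells x n_pcs score matrix) and
#'   `var_frac` (all component variance fractions, non-increasing, sum 1)
#' @export
run_pca <- function(em, panel, n_pcs = 50) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  genes <- if (inherits(panel, "HVGPanel")) panel$gene else as.character(panel)
  missing <- setdiff(genes, em$gene_ids)
  if (length(missing)) stop("panel gene(s) absent from matrix: ",
                            paste(utils::head(missing, 3), collapse = ", "))
  x <- t(em$values[genes, , drop = FALSE])        # cells x genes
  sds <- apply(x, 2, stats::sd)
  x <- x[, sds > 0, drop = FALSE]
  if (!ncol(x)) stop("no non-constant genes in panel")
  x <- scale(x, center = TRUE, scale = TRUE)
  max_pcs <- min(nrow(x) - 1L, ncol(x))
  if (n_pcs > max_pcs)
    stop("n_pcs = ", n_pcs, " exceeds available rank ", max_pcs)
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  var_all <- pc$sdev^2
  coords <- pc$x[, seq_len(n_pcs), drop = FALSE]
  rownames(coords) <- em$cell_ids
  structure(list(coords = coords, var_frac = var_all / sum(var_all),
                 n_genes = ncol(x)),
            class = "Embedding")
}

#' @export
print.Embedding <- function(x, ...) {
  cat(sprintf("Embedding: %d cells x %d components (top-%d cumulative variance %.1f%%)\n",
              nrow(x$coords), ncol(x$coords), ncol(x$coords),
              100 * sum(x$var_frac[seq_len(min(ncol(x$coords), length(x$var_frac)))])))
  invisible(x)
}

#' Flag outlier cells in PC space
#'
#' A cell is flagged when its robust z-score, |x - median| / (1.4826 * MAD),
#' exceeds `z_max` on any of the top 10 components. Components with zero MAD
#' are skipped with a warning. Note that rare genuine subpopulations can look
#' like outliers under this rule; the pipeline therefore leaves it off by
#' default.
#'
#' @param embedding an `Embedding` with >= 2 components
#' @param z_max robust z threshold
#' @return named logical vector, TRUE = flagged
#' @export
flag_outliers <- function(embedding, z_max) {
  co <- embedding$coords
  if (ncol(co) < 2) stop("need >= 2 components")
  flag <- rep(FALSE, nrow(co))
  if (!is.finite(z_max)) return(stats::setNames(flag, rownames(co)))
  for (j in seq_len(min(10L, ncol(co)))) {
    m <- stats::median(co[, j])
    s <- 1.4826 * stats::mad(co[, j], constant = 1)
    if (s == 0) {
      warning("component ", j, " has zero MAD; skipped")
      next
    }
    flag <- flag | (abs(co[, j] - m) / s > z_max)
  }
  stats::setNames(flag, rownames(co))
}

# Symmetric (union) KNN graph on Euclidean distances in PC space.
knn_graph <- function(coords, k) {
  n <- nrow(coords)
  if (k >= n) k <- n - 1L
  d <- as.matrix(stats::dist(coords))
  edges <- matrix(0L, 0, 2)
  for (i in seq_len(n)) {
    ord <- order(d[i, ])
    ord <- ord[ord != i]          # ties can sort self anywhere
    nb <- ord[seq_len(k)]
    edges <- rbind(edges, cbind(i, nb))
  }
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  g <- igraph::as_undirected(g, mode = "collapse")
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::V(g)$name <- rownames(coords)
  g
}

#' KNN/Louvain clustering over a resolution sweep
#'
#' Builds the symmetric k-nearest-neighbour graph once (union of directed
#' edges, Euclidean in PC space) and runs Louvain modularity optimization at
#' each resolution. Deterministic under a fixed seed. A disconnected graph is
#' clustered per component with a warning (Louvain handles this natively).
#'
#' @param embedding an `Embedding`
#' @param k neighbours per cell (default 10)
#' @param resolutions resolution grid (default `seq(0.8, 2, by = 0.2)`)
#' @param seed RNG seed for the community search
#' @return named list (one per resolution) of `ClusterAssignment`s: integer
#'   labels 1..K named by cell, labels renumbered by decreasing cluster size,
#'   with attributes `resolution` and `K`
#' @export
cluster_louvain_sweep <- function(embedding, k = 10,
                                  resolutions = seq(0.8, 2, by = 0.2),
                                  seed = 0) {
  coords <- embedding$coords
  if (k >= nrow(coords)) k <- nrow(coords) - 1L
  g <- knn_graph(coords, k)
  if (igraph::count_components(g) > 1L)
    warning("KNN graph is disconnected; components are clustered independently")
  out <- list()
  for (res in resolutions) {
    cl <- with_seed(derive_seed(seed, paste0("louvain", res)),
                    igraph::cluster_louvain(g, resolution = res))
    lab <- as.integer(igraph::membership(cl))
    out[[sprintf("%.1f", res)]] <- relabel_by_size(
      stats::setNames(lab, rownames(coords)), resolution = res)
  }
  out
}

#' Build a ClusterAssignment with labels renumbered 1..K by decreasing size
#'
#' @param labels named integer vector (cell -> raw label)
#' @param resolution,history provenance carried as attributes
#' @return a `ClusterAssignment`
#' @export
relabel_by_size <- function(labels, resolution = NA_real_, history = list()) {
  tab <- sort(table(labels), decreasing = TRUE)
  map <- stats::setNames(seq_along(tab), names(tab))
  new <- as.integer(map[as.character(labels)])
  structure(stats::setNames(new, names(labels)),
            resolution = resolution, K = length(tab), history = history,
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: %d cells, K = %d (resolution %s)\n",
              length(x), attr(x, "K"), format(attr(x, "resolution"))))
  invisible(x)
}

#' Precompute the per-gene rank structures used by [identify_degs()]
#'
#' Ranks, tie-correction terms and expression-scale values depend only on the
#' matrix and cell set, so the resolution sweep and merge loop share them.
#'
#' @param em log-scale ExpressionMatrix
#' @param cells cell ids (default all)
#' @return opaque list consumed by [identify_degs()]
#' @export
deg_engine <- function(em, cells = em$cell_ids) {
  x <- em$values[, cells, drop = FALSE]
  rank_mat <- t(apply(x, 1, rank))
  tie_term <- apply(rank_mat, 1, function(r) {
    tt <- rle(sort(r))$lengths
    sum(tt^3 - tt)
  })
  list(cells = cells, rank_mat = rank_mat, tie_term = tie_term,
       expr = expm1(x))
}

# Vectorized two-sided Wilcoxon rank-sum (normal approximation with tie
# correction and continuity correction), cluster vs rest, for every gene at
# once. Cross-checked against stats::wilcox.test in the test suite.
rank_sum_test <- function(rank_mat, tie_term, in_group) {
  n1 <- sum(in_group); n2 <- ncol(rank_mat) - n1; n <- n1 + n2
  R1 <- rank_mat[, in_group, drop = FALSE]
  W <- rowSums(R1) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  z <- W - mu
  cc <- sign(z) * 0.5
  sigma <- sqrt(pmax(sigma2, 0))
  p <- ifelse(sigma == 0, 1, 2 * stats::pnorm(-abs((z - cc) / sigma)))
  pmin(p, 1)
}

#' Cluster-vs-rest differential expression
#'
#' For each cluster, every gene is tested against the pooled remaining cells
#' by a two-sided Wilcoxon rank-sum on log values, with Benjamini-Hochberg
#' correction across genes within the cluster. A gene is called a DEG when
#' q < `q_max` and |log2 fold change| > `lfc_min`; the fold change is the
#' log2 ratio of group means on the expression (expm1) scale. Size-1 clusters
#' are skipped with a warning.
#'
#' @param em log-scale ExpressionMatrix (all genes, not only HVGs)
#' @param assignment a `ClusterAssignment` covering `em`'s cells
#' @param q_max,lfc_min DEG thresholds (defaults 0.05, 0.25)
#' @param engine precomputed [deg_engine()] for repeated calls on the same
#'   matrix/cells (the merge loop and resolution sweep reuse it)
#' @return data.frame (cluster, gene, log2fc, p, q, direction, deg)
#' @export
identify_degs <- function(em, assignment, q_max = 0.05, lfc_min = 0.25,
                          engine = NULL) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  cells <- names(assignment)
  if (!all(cells %in% em$cell_ids)) stop("assignment cells absent from matrix")
  ks <- sort(unique(as.integer(assignment)))
  if (length(ks) < 2) stop("need >= 2 clusters for DEG calling")
  if (is.null(engine)) engine <- deg_engine(em, cells)
  if (!identical(engine$cells, cells))
    stop("engine was built for a different cell set")
  rank_mat <- engine$rank_mat
  tie_term <- engine$tie_term
  expr <- engine$expr
  out <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    kk <- ks[i]
    in_g <- as.integer(assignment) == kk
    if (sum(in_g) < 2) {
      warning("cluster ", kk, " has fewer than 2 cells; skipped")
      next
    }
    p <- rank_sum_test(rank_mat, tie_term, in_g)
    q <- stats::p.adjust(p, method = "BH")
    m1 <- rowMeans(expr[, in_g, drop = FALSE])
    m0 <- rowMeans(expr[, !in_g, drop = FALSE])
    l2 <- ifelse(m1 == 0 & m0 == 0, 0, log2(m1) - log2(m0))
    out[[i]] <- data.frame(
      cluster = kk, gene = em$gene_ids, log2fc = l2, p = p, q = q,
      direction = ifelse(l2 >= 0, "up", "down"),
      deg = q < q_max & abs(l2) > lfc_min & is.finite(p),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# Upregulated DEG count of cluster cells_a against cluster cells_b
# (Wilcoxon rank-sum within the pair, BH across genes, same thresholds as
# identify_degs).
pairwise_up_degs <- function(em, cells_a, cells_b, q_max, lfc_min) {
  x <- em$values[, c(cells_a, cells_b), drop = FALSE]
  rank_mat <- t(apply(x, 1, rank))
  tie_term <- apply(rank_mat, 1, function(r) {
    tt <- rle(sort(r))$lengths
    sum(tt^3 - tt)
  })
  in_g <- c(rep(TRUE, length(cells_a)), rep(FALSE, length(cells_b)))
  p <- rank_sum_test(rank_mat, tie_term, in_g)
  q <- stats::p.adjust(p, method = "BH")
  m1 <- rowMeans(expm1(x[, in_g, drop = FALSE]))
  m0 <- rowMeans(expm1(x[, !in_g, drop = FALSE]))
  l2 <- ifelse(m1 == 0 & m0 == 0, 0, log2(m1) - log2(m0))
  sum(q < q_max & l2 > lfc_min & is.finite(p))
}

#' Merge clusters with few distinguishing upregulated DEGs
#'
#' Guards against excessive classification: a raw cluster that cannot be
#' distinguished from its closest neighbour does not deserve to be its own
#' state. Iteratively, each cluster is tested against the cluster with the
#' nearest PC-space centroid (Wilcoxon rank-sum per gene, BH within the test,
#' upregulated at q < `q_max` and log2FC > `lfc_min`); the cluster with the
#' fewest such upregulated DEGs, if below `min_up_degs`, is merged into that
#' nearest neighbour, and the counts are recomputed. Terminates when every
#' cluster passes or K = 1. The test is against the nearest cluster rather
#' than the pooled rest because two halves of a randomly over-split cluster
#' inherit all of the parent's markers against the rest and would never be
#' re-merged under a cluster-vs-rest count. Labels stay contiguous 1..K; the
#' merge history is recorded.
#'
#' @param em log-scale ExpressionMatrix
#' @param assignment a `ClusterAssignment`
#' @param embedding the `Embedding` used for clustering (centroid distances)
#' @param min_up_degs threshold (default 10); 0 is a no-op
#' @param q_max,lfc_min DEG thresholds (shared with [identify_degs()])
#' @param engine precomputed [deg_engine()] for the final cluster-vs-rest
#'   DEG table
#' @return list with `assignment` (merged) and `degs` (final cluster-vs-rest
#'   DEG table from [identify_degs()])
#' @export
merge_few_deg_clusters <- function(em, assignment, embedding,
                                   min_up_degs = 10, q_max = 0.05,
                                   lfc_min = 0.25, engine = NULL,
                                   cache = NULL) {
  history <- attr(assignment, "history") %||% list()
  cells <- names(assignment)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  memo_pair <- function(a, b) {
    key <- paste(c(a, "|", b), collapse = ",")
    if (is.null(cache[[key]]))
      cache[[key]] <- pairwise_up_degs(em, a, b, q_max, lfc_min)
    cache[[key]]
  }
  repeat {
    ks <- sort(unique(as.integer(assignment)))
    if (length(ks) == 1L || min_up_degs <= 0) break
    cent <- centroids(embedding$coords[cells, , drop = FALSE], assignment)
    d <- as.matrix(stats::dist(cent))
    diag(d) <- Inf
    nearest <- ks[apply(d, 1, which.min)]
    up <- vapply(seq_along(ks), function(i) {
      a <- cells[as.integer(assignment) == ks[i]]
      b <- cells[as.integer(assignment) == nearest[i]]
      memo_pair(a, b)
    }, numeric(1))
    i_worst <- which.min(up)
    if (up[i_worst] >= min_up_degs) break
    worst <- ks[i_worst]
    into <- nearest[i_worst]
    history[[length(history) + 1L]] <- c(from = worst, into = into)
    lab <- as.integer(assignment)
    lab[lab == worst] <- into
    assignment <- relabel_by_size(stats::setNames(lab, cells),
                                  resolution = attr(assignment, "resolution"),
                                  history = history)
  }
  if (is.null(engine)) engine <- deg_engine(em, cells)
  degs <- if (attr(assignment, "K") >= 2L)
    identify_degs(em, assignment, q_max, lfc_min, engine) else NULL
  attr(assignment, "history") <- history
  list(assignment = assignment, degs = degs)
}

centroids <- function(coords, assignment) {
  ks <- sort(unique(as.integer(assignment)))
  cent <- t(vapply(ks, function(kk)
    colMeans(coords[as.integer(assignment) == kk, , drop = FALSE]),
    numeric(ncol(coords))))
  rownames(cent) <- ks
  cent
}

#' Two-dimensional stochastic-neighbour embedding of the PC scores
#'
#' Visualization only; no downstream stage consumes it. Deterministic under a
#' fixed seed. Requires the Rtsne package.
#'
#' @param embedding an `Embedding`
#' @param perplexity tSNE perplexity (default 10); must be < (n_cells - 1) / 3
#' @param seed RNG seed
#' @return cells x 2 coordinate matrix
#' @export
embed_2d <- function(embedding, perplexity = 10, seed = 0) {
  co <- embedding$coords
  if (perplexity >= (nrow(co) - 1) / 3)
    stop("perplexity ", perplexity, " too large for ", nrow(co), " cells")
  if (!requireNamespace("Rtsne", quietly = TRUE))
    stop("embed_2d requires the Rtsne package")
  y <- with_seed(derive_seed(seed, "tsne"),
                 Rtsne::Rtsne(co, dims = 2, perplexity = perplexity,
                              pca = FALSE, max_iter = 500)$Y)
  rownames(y) <- rownames(co)
  colnames(y) <- c("tsne1", "tsne2")
  y
}

#' Full clustering stage: PCA, sweep, merge, resolution selection
#'
#' Runs [run_pca()], optionally removes PCA outliers, sweeps Louvain
#' resolutions, merges few-DEG clusters at every resolution, and selects the
#' smallest resolution whose post-merge cluster count is stable across two
#' consecutive grid points (falling back to the last resolution).
#'
#' @param em log-scale ExpressionMatrix
#' @param panel `HVGPanel`
#' @param n_pcs,k,resolutions,min_up_degs,q_max,lfc_min,seed stage parameters
#' @param outlier_z robust-z threshold for PCA outlier removal (default Inf:
#'   off; see [flag_outliers()])
#' @return list: `embedding`, `assignment` (final), `degs`, `sweep` (per
#'   resolution post-merge assignments), `resolution`, `outliers`
#' @export
cluster_cells <- function(em, panel, n_pcs = 50, k = 10,
                          resolutions = seq(0.8, 2, by = 0.2),
                          min_up_degs = 10, q_max = 0.05, lfc_min = 0.25,
                          outlier_z = Inf, seed = 0) {
  emb <- run_pca(em, panel, n_pcs)
  out_flag <- flag_outliers(emb, outlier_z)
  if (any(out_flag)) {
    msg("removing ", sum(out_flag), " PCA outlier cell(s)")
    em <- em_subset(em, cells = which(!(em$cell_ids %in% names(which(out_flag)))))
    emb <- run_pca(em, panel, n_pcs)
  }
  sweep_raw <- cluster_louvain_sweep(emb, k = k, resolutions = resolutions,
                                     seed = seed)
  engine <- deg_engine(em, em$cell_ids)
  pair_cache <- new.env(parent = emptyenv())
  merged <- lapply(sweep_raw, function(a)
    merge_few_deg_clusters(em, a, emb, min_up_degs, q_max, lfc_min, engine,
                           cache = pair_cache))
  Ks <- vapply(merged, function(m) attr(m$assignment, "K"), numeric(1))
  pick <- length(Ks)
  for (i in seq_len(length(Ks) - 1L)) {
    if (Ks[i] == Ks[i + 1L]) { pick <- i; break }
  }
  res <- resolutions[pick]
  msg("resolution sweep K: ", paste(Ks, collapse = " "),
      " -> chose resolution ", res, " (K = ", Ks[pick], ")")
  list(embedding = emb, assignment = merged[[pick]]$assignment,
       degs = merged[[pick]]$degs,
       sweep = lapply(merged, `[[`, "assignment"),
       resolution = res, outliers = out_flag)
}
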