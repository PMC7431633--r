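# Cluster-rooted lineage inference: MST over cluster centroids, per-lineage
# principal-curve pseudotime with projection weights, HVG-panel stability.

#' Infer lineages as root-to-leaf paths of a centroid MST
#'
#' Cluster centroids are the per-cluster means of the first `n_dims` PC
#' coordinates; the minimum spanning tree is computed on pairwise Euclidean
#' centroid distances (deterministic tie-break by sorted label pair), and
#' lineages are all root-to-leaf paths, enumerated in leaf label order.
#'
#' @param embedding an `Embedding`
#' @param assignment a `ClusterAssignment` (K >= 2)
#' @param root_cluster label of the starting cluster
#' @param n_dims number of leading components for centroid distances
#'   (default 10)
#' @return a `LineageTree`: list with `centroids`, `edges` (two-column label
#'   matrix), `root`, `lineages` (list of integer label paths)
#' @export
infer_lineages <- function(embedding, assignment, root_cluster, n_dims = 10) {
  ks <- sort(unique(as.integer(assignment)))
  if (length(ks) < 2) stop("need K >= 2 clusters")
  if (!root_cluster %in% ks)
    stop("root cluster ", root_cluster, " not present in assignment")
  co <- embedding$coords[names(assignment), seq_len(min(n_dims, ncol(embedding$coords))),
                         drop = FALSE]
  cent <- centroids(co, assignment)
  d <- as.matrix(stats::dist(cent))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g, algorithm = "prim")
  el <- igraph::as_edgelist(mst)
  el <- t(apply(el, 1, function(e) sort(as.integer(e))))
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  tree <- igraph::graph_from_edgelist(matrix(as.character(el), ncol = 2),
                                      directed = FALSE)
  deg <- igraph::degree(tree)
  leaves <- setdiff(names(deg)[deg == 1], as.character(root_cluster))
  if (!length(leaves)) leaves <- setdiff(names(deg), as.character(root_cluster))
  leaves <- leaves[order(as.integer(leaves))]
  lineages <- lapply(leaves, function(lf) {
    p <- igraph::shortest_paths(tree, from = as.character(root_cluster),
                                to = lf)$vpath[[1]]
    as.integer(names(p))
  })
  names(lineages) <- paste0("L", seq_along(lineages))
  structure(list(centroids = cent, edges = el, root = as.integer(root_cluster),
                 lineages = lineages),
            class = "LineageTree")
}

#' @export
print.LineageTree <- function(x, ...) {
  cat("LineageTree rooted at cluster ", x$root, ":\n", sep = "")
  for (nm in names(x$lineages))
    cat("  ", nm, ": ", paste(x$lineages[[nm]], collapse = " -> "), "\n", sep = "")
  invisible(x)
}

# Project points onto a polyline (vertices v, ordered). Returns arc-length
# positions, distances and the projected points.
project_polyline <- function(points, v) {
  nseg <- nrow(v) - 1L
  seg_len <- sqrt(rowSums((v[-1L, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg_len))
  n <- nrow(points)
  best_d2 <- rep(Inf, n); best_t <- numeric(n)
  proj <- matrix(0, n, ncol(v))
  for (s in seq_len(nseg)) {
    a <- v[s, ]; b <- v[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    tt <- if (len2 == 0) rep(0, n) else
      pmin(1, pmax(0, as.numeric(sweep(points, 2, a) %*% ab) / len2))
    pp <- matrix(a, n, ncol(v), byrow = TRUE) + outer(tt, ab)
    d2 <- rowSums((points - pp)^2)
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_t[upd] <- cum[s] + tt[upd] * sqrt(len2)
    proj[upd, ] <- pp[upd, , drop = FALSE]
  }
  list(lambda = best_t, dist = sqrt(best_d2), proj = proj)
}

# One principal-curve iteration: order cells by pseudotime and re-fit each
# coordinate by a sliding-window local mean over the ordered cells.
smooth_curve <- function(points, lambda, window) {
  ord <- order(lambda)
  n <- length(ord)
  half <- max(2L, floor(window / 2))
  sm <- matrix(0, n, ncol(points))
  x <- points[ord, , drop = FALSE]
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    sm[i, ] <- colMeans(x[lo:hi, , drop = FALSE])
  }
  sm
}

#' Principal-curve pseudotime along each lineage
#'
#' Per lineage, a curve is initialized as the polyline through the lineage's
#' cluster centroids (root first). The iteration alternates projection of the
#' lineage's member cells onto the curve (pseudotime = arc length at the
#' projection) with re-fitting each coordinate as a sliding-window local mean
#' of the ordered cells (window 10% of lineage cells, minimum 5), until the
#' mean movement of projected points falls below `tol` times the RMS radius
#' of the lineage's point cloud, or `max_iter` is reached (warning on
#' non-convergence). Cells are weighted across the
#' lineages containing their cluster by a Gaussian kernel in projection
#' distance, exp(-d^2 / sigma^2) with sigma the median projection distance
#' over all (cell, lineage) pairs, normalized to sum to 1 per cell; entries
#' with weight below `weight_cutoff` are marked not retained.
#'
#' @param embedding an `Embedding`
#' @param assignment a `ClusterAssignment`
#' @param tree a `LineageTree` from [infer_lineages()]
#' @param weight_cutoff retention threshold on the projection weight
#'   (default 0.6)
#' @param tol relative convergence tolerance on mean projected-point movement
#'   (default 0.01; a fraction of the point cloud's RMS radius)
#' @param max_iter maximum curve-fitting iterations (default 15)
#' @param n_dims leading components used (default 10, as in the tree)
#' @return a `PseudotimeAssignment`: data.frame (cell, lineage, pseudotime,
#'   dist, weight, retained) with attribute `sigma`
#' @export
fit_pseudotime <- function(embedding, assignment, tree, weight_cutoff = 0.6,
                           tol = 0.01, max_iter = 15, n_dims = 10) {
  co <- embedding$coords[names(assignment), seq_len(min(n_dims, ncol(embedding$coords))),
                         drop = FALSE]
  lab <- as.integer(assignment)
  res <- list()
  for (ln in names(tree$lineages)) {
    path <- tree$lineages[[ln]]
    member <- lab %in% path
    if (sum(member) < 4)
      stop("lineage ", ln, " has fewer than 4 cells")
    pts <- co[member, , drop = FALSE]
    curve <- tree$centroids[as.character(path), , drop = FALSE]
    window <- max(5L, ceiling(0.1 * nrow(pts)))
    rms <- sqrt(mean(rowSums(sweep(pts, 2, colMeans(pts))^2)))
    thresh <- tol * max(rms, .Machine$double.eps)
    pr <- project_polyline(pts, curve)
    for (it in seq_len(max_iter)) {
      curve <- smooth_curve(pts, pr$lambda, window)
      # collapse duplicate consecutive vertices to keep segments well defined
      keep <- c(TRUE, rowSums(abs(diff(curve))) > 0)
      pr_new <- project_polyline(pts, curve[keep, , drop = FALSE])
      move <- mean(sqrt(rowSums((pr_new$proj - pr$proj)^2)))
      pr <- pr_new
      if (move < thresh) break
      if (it == max_iter)
        warning("lineage ", ln, ": curve fit did not converge in ",
                max_iter, " iterations (last movement ", signif(move, 3), ")")
    }
    res[[ln]] <- data.frame(cell = rownames(pts), lineage = ln,
                            pseudotime = pr$lambda, dist = pr$dist,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  sigma <- stats::median(out$dist)
  if (sigma == 0) sigma <- mean(out$dist) + .Machine$double.eps
  out$weight <- exp(-(out$dist / sigma)^2)
  tot <- tapply(out$weight, out$cell, sum)
  out$weight <- out$weight / as.numeric(tot[out$cell])
  out$retained <- out$weight >= weight_cutoff
  rownames(out) <- NULL
  attr(out, "sigma") <- sigma
  attr(out, "weight_cutoff") <- weight_cutoff
  class(out) <- c("PseudotimeAssignment", "data.frame")
  out
}

#' Lineage stability across HVG panel sizes
#'
#' Reruns HVG selection, PCA/Louvain clustering and lineage inference at each
#' panel size and reports whether the multiset of lineage cluster-paths is
#' identical across panels after matching cluster labels to the first panel's
#' clustering by maximal cell overlap.
#'
#' @param em log-scale ExpressionMatrix (already cell/gene filtered)
#' @param panel_sizes HVG panel sizes (conventionally 2500, 5000, 8000)
#' @param config pipeline parameters; see [pipeline_config()]
#' @param gene_sets named list of gene sets for per-panel root selection
#'   (unneeded when `config$root_cluster` is set)
#' @return list: `stable` (logical), `lineages` (per panel, matched label
#'   paths), `assignments`
#' @export
check_panel_stability <- function(em, panel_sizes = c(2500, 5000, 8000),
                                  config = pipeline_config(),
                                  gene_sets = NULL) {
  runs <- list()
  for (ps in panel_sizes) {
    panel <- select_hvgs(em, target_size = ps, n_bins = config$hvg_bins)
    cl <- cluster_cells(em, panel, n_pcs = config$n_pcs, k = config$knn_k,
                        resolutions = config$resolutions,
                        min_up_degs = config$min_up_degs,
                        q_max = config$deg_q, lfc_min = config$deg_lfc,
                        seed = config$seed)
    root <- pick_root(em, cl$assignment, config, gene_sets)
    tree <- infer_lineages(cl$embedding, cl$assignment, root,
                           n_dims = config$mst_dims)
    runs[[as.character(ps)]] <- list(assignment = cl$assignment, tree = tree)
  }
  ref <- runs[[1L]]$assignment
  paths <- lapply(runs, function(r) {
    map <- match_labels(r$assignment, ref)
    sort(vapply(r$tree$lineages, function(p)
      paste(map[as.character(p)], collapse = "-"), character(1)))
  })
  stable <- all(vapply(paths, identical, logical(1), y = paths[[1L]]))
  list(stable = stable, lineages = paths,
       assignments = lapply(runs, `[[`, "assignment"))
}

# Map labels of `a` onto labels of `ref` by greedy maximal cell overlap.
match_labels <- function(a, ref) {
  ka <- sort(unique(as.integer(a)))
  ov <- outer(ka, sort(unique(as.integer(ref))), Vectorize(function(i, j)
    sum(names(a)[as.integer(a) == i] %in% names(ref)[as.integer(ref) == j])))
  map <- stats::setNames(rep(NA_integer_, length(ka)), ka)
  kr <- sort(unique(as.integer(ref)))
  ovm <- ov
  for (step in seq_len(min(length(ka), length(kr)))) {
    ij <- which(ovm == max(ovm), arr.ind = TRUE)[1, ]
    map[as.character(ka[ij[1]])] <- kr[ij[2]]
    ovm[ij[1], ] <- -1; ovm[, ij[2]] <- -1
  }
  unmapped <- is.na(map)
  if (any(unmapped)) map[unmapped] <- max(kr) + seq_len(sum(unmapped))
  map
}
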