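#' Expression matrix container
#'
#' The substrate of every pipeline stage: a dense non-negative genes x cells
#' (or genes x bulk samples) matrix with unique row and column identifiers and
#' a scale tag recording whether values are raw counts, RPKM/FPKM-like
#' normalized abundances, or log-transformed.
#'
#' @param values numeric matrix, genes as rows, cells/samples as columns
#' @param gene_ids character vector of unique gene ids (defaults to rownames)
#' @param cell_ids character vector of unique cell/sample ids (defaults to
#'   colnames)
#' @param scale_tag one of `"counts"`, `"rpkm"`, `"log"`; `"log"` is only set
#'   by [log_transform()]
#' @return an object of class `ExpressionMatrix`
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              cell_ids = colnames(values),
                              scale_tag = c("counts", "rpkm", "log")) {
  scale_tag <- match.arg(scale_tag)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene_ids and cell_ids are required (rownames/colnames or explicit)")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(values) || length(cell_ids) != ncol(values))
    stop("dimension mismatch: ", nrow(values), "x", ncol(values), " values vs ",
         length(gene_ids), " gene ids and ", length(cell_ids), " cell ids")
  dup_g <- gene_ids[duplicated(gene_ids)]
  if (length(dup_g)) stop("duplicate gene id: ", dup_g[[1L]])
  dup_c <- cell_ids[duplicated(cell_ids)]
  if (length(dup_c)) stop("duplicate cell id: ", dup_c[[1L]])
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative value at gene %s, cell %s (%g)",
                 gene_ids[neg[1, 1]], cell_ids[neg[1, 2]],
                 values[neg[1, 1], neg[1, 2]]))
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 scale_tag = scale_tag),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells [%s]\n",
              length(x$gene_ids), length(x$cell_ids), x$scale_tag))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an expression matrix by gene and/or cell position or id
#'
#' Preserves order and re-validates the container invariants.
#' @param em an [expression_matrix()]
#' @param genes,cells index vectors (positions, ids or logical); `NULL` keeps
#'   all
#' @return an `ExpressionMatrix`
#' @export
em_subset <- function(em, genes = NULL, cells = NULL) {
  v <- em$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(cells)) v <- v[, cells, drop = FALSE]
  expression_matrix(v, scale_tag = em$scale_tag)
}

#' Read an expression matrix
#'
#' Two on-disk dialects are supported: a dense TSV with genes as rows, a
#' header row of cell ids and a leading `gene` column, and a MatrixMarket
#' coordinate triplet (`.mtx`) with companion one-id-per-line gene and cell
#' files. Ids are kept in file order.
#'
#' @param path file path; for `format = "mtx"` the `.mtx` file
#' @param format `"tsv"` or `"mtx"`
#' @param genes_path,cells_path companion id files (mtx only); default
#'   `<path>.genes.txt` / `<path>.cells.txt`
#' @param scale_tag scale of the stored values (default `"rpkm"`)
#' @return an [expression_matrix()]
#' @export
read_expression_matrix <- function(path, format = c("tsv", "mtx"),
                                   genes_path = NULL, cells_path = NULL,
                                   scale_tag = "rpkm") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                            colClasses = c("character"), stringsAsFactors = FALSE)
    gene_ids <- df[[1L]]
    vals <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(vals) <- "double"
    expression_matrix(vals, gene_ids = gene_ids, cell_ids = colnames(df)[-1L],
                      scale_tag = scale_tag)
  } else {
    genes_path <- genes_path %||% paste0(path, ".genes.txt")
    cells_path <- cells_path %||% paste0(path, ".cells.txt")
    if (!file.exists(genes_path)) stop("no such file: ", genes_path)
    if (!file.exists(cells_path)) stop("no such file: ", cells_path)
    m <- Matrix::readMM(path)
    gene_ids <- readLines(genes_path)
    cell_ids <- readLines(cells_path)
    expression_matrix(as.matrix(m), gene_ids = gene_ids, cell_ids = cell_ids,
                      scale_tag = scale_tag)
  }
}

#' Write an expression matrix
#'
#' @param em an [expression_matrix()]
#' @param path output path
#' @param format `"tsv"` (dense, reference dialect) or `"mtx"` (MatrixMarket
#'   triplet plus `<path>.genes.txt` / `<path>.cells.txt`)
#' @return `path`, invisibly
#' @export
write_expression_matrix <- function(em, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (format == "tsv") {
    df <- data.frame(gene = em$gene_ids, em$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("gene", em$cell_ids)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(em$values, sparse = TRUE), path)
    writeLines(em$gene_ids, paste0(path, ".genes.txt"))
    writeLines(em$cell_ids, paste0(path, ".cells.txt"))
  }
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene...`.
#' Within-set duplicates are dropped with a warning; a set that is empty after
#' deduplication is an error.
#'
#' @param path GMT file
#' @return named list of character vectors (set name -> gene ids), file order
#' @export
read_gene_sets_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields")
    genes <- f[-c(1L, 2L)]
    if (anyDuplicated(genes)) {
      warning("GMT set '", f[[1L]], "' (line ", i, ") contains duplicate genes; deduplicated")
      genes <- unique(genes)
    }
    if (!length(genes)) stop("GMT set '", f[[1L]], "' empty after deduplication")
    sets[[f[[1L]]]] <- genes
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors
#' @param path output file
#' @export
write_gene_sets_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Motif-ranking database
#'
#' Whole-genome motif rankings of the kind distributed with SCENIC: per motif,
#' an integer rank of every gene (1 = strongest motif-target affinity), plus an
#' annotation mapping motifs to the transcription factor they belong to.
#'
#' @param ranks integer matrix, motifs x genes; each row must be a permutation
#'   of `1..G`
#' @param motif_to_tf named character vector: motif id -> TF gene id; every TF
#'   must be present in the gene universe (the rank matrix columns)
#' @return an object of class `MotifRankingDB`
#' @export
motif_ranking_db <- function(ranks, motif_to_tf) {
  ranks <- as.matrix(ranks)
  G <- ncol(ranks)
  if (is.null(rownames(ranks)) || is.null(colnames(ranks)))
    stop("ranks must have motif rownames and gene colnames")
  for (i in seq_len(nrow(ranks))) {
    r <- ranks[i, ]
    if (length(r) != G || anyNA(r) || !all(sort(as.integer(r)) == seq_len(G)))
      stop("rank row for motif '", rownames(ranks)[i],
           "' is not a permutation of 1..", G)
  }
  storage.mode(ranks) <- "integer"
  motif_to_tf <- motif_to_tf[names(motif_to_tf) %in% rownames(ranks)]
  missing_ann <- setdiff(rownames(ranks), names(motif_to_tf))
  if (length(missing_ann)) {
    warning("dropping ", length(missing_ann), " motif(s) without TF annotation: ",
            paste(missing_ann, collapse = ", "))
    ranks <- ranks[setdiff(rownames(ranks), missing_ann), , drop = FALSE]
  }
  bad_tf <- setdiff(unique(motif_to_tf), colnames(ranks))
  if (length(bad_tf))
    stop("annotation maps to TF(s) absent from the gene universe: ",
         paste(bad_tf, collapse = ", "))
  structure(list(ranks = ranks, motif_ids = rownames(ranks),
                 gene_ids = colnames(ranks),
                 motif_to_tf = motif_to_tf[rownames(ranks)]),
            class = "MotifRankingDB")
}

#' @export
print.MotifRankingDB <- function(x, ...) {
  cat(sprintf("MotifRankingDB: %d motifs x %d genes, %d TFs\n",
              nrow(x$ranks), ncol(x$ranks), length(unique(x$motif_to_tf))))
  invisible(x)
}

#' Read a motif-ranking database
#'
#' @param path_ranks TSV, motifs as rows (leading `motif` column), genes as
#'   columns, integer ranks
#' @param path_annotation two-column TSV (`motif`, `tf`) with a header;
#'   annotation rows referencing absent motifs are skipped with a warning
#' @return a [motif_ranking_db()]
#' @export
read_motif_rankings <- function(path_ranks, path_annotation) {
  if (!file.exists(path_ranks)) stop("no such file: ", path_ranks)
  if (!file.exists(path_annotation)) stop("no such file: ", path_annotation)
  df <- utils::read.table(path_ranks, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ranks <- as.matrix(df[, -1L, drop = FALSE])
  rownames(ranks) <- df[[1L]]
  ann <- utils::read.table(path_annotation, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  unknown <- !(ann[[1L]] %in% rownames(ranks))
  if (any(unknown)) {
    warning("annotation references absent motif(s): ",
            paste(ann[[1L]][unknown], collapse = ", "), "; skipped")
    ann <- ann[!unknown, , drop = FALSE]
  }
  motif_to_tf <- stats::setNames(as.character(ann[[2L]]), ann[[1L]])
  motif_ranking_db(ranks, motif_to_tf)
}

#' Write a motif-ranking database
#' @param db a [motif_ranking_db()]
#' @param path_ranks,path_annotation output TSV paths
#' @export
write_motif_rankings <- function(db, path_ranks, path_annotation) {
  df <- data.frame(motif = db$motif_ids, db$ranks, check.names = FALSE)
  colnames(df) <- c("motif", db$gene_ids)
  utils::write.table(df, path_ranks, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(motif = names(db$motif_to_tf),
                                tf = unname(db$motif_to_tf)),
                     path_annotation, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path_ranks)
}

#' Bulk passage series
#'
#' An [expression_matrix()] whose columns are consecutive cultivation passages
#' (e.g. PD6..PD11) in a meaningful, preserved order.
#'
#' @param em an `ExpressionMatrix` on FPKM scale with >= 3 samples
#' @return object of class `c("BulkSeries","ExpressionMatrix")`
#' @export
bulk_series <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (length(em$cell_ids) < 3L)
    stop("a bulk passage series needs >= 3 samples")
  class(em) <- c("BulkSeries", class(em))
  em
}
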