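# Shared fixtures, built once per test session and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

tiny_data <- function(seed = 1) {
  cached(paste0("tiny", seed), generate_dataset(preset_config("tiny"), seed = seed))
}

tiny_config <- function(...) {
  pipeline_config(min_detected_genes = 50, hvg_size = 200, n_pcs = 20,
                  mst_dims = 5, perplexity = 5, ...)
}

tiny_run <- function(seed = 1) {
  cached(paste0("tinyrun", seed),
         suppressWarnings(suppressMessages(
           run_pipeline(tiny_data(seed), tiny_config()))))
}

# Small dense matrix fixture: genes x cells with ids.
toy_em <- function(values, scale_tag = "rpkm", gene_prefix = "g",
                   cell_prefix = "c") {
  values <- as.matrix(values)
  expression_matrix(values,
                    gene_ids = paste0(gene_prefix, seq_len(nrow(values))),
                    cell_ids = paste0(cell_prefix, seq_len(ncol(values))),
                    scale_tag = scale_tag)
}

# Two well-separated Gaussian blobs in gene space (log scale), n cells each;
# each blob carries its own upregulated marker block.
two_blob_em <- function(n = 20, g = 40, shift = 4, seed = 42) {
  set.seed(seed)
  x <- matrix(abs(rnorm(g * 2 * n, 1, 0.2)), g, 2 * n)
  half <- seq_len(g / 2)
  x[half, seq_len(n)] <- x[half, seq_len(n)] + shift
  x[setdiff(seq_len(g), half), n + seq_len(n)] <-
    x[setdiff(seq_len(g), half), n + seq_len(n)] + shift
  toy_em(x, scale_tag = "log")
}
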