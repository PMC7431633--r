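#!/usr/bin/env Rscript
# Dimension reduction and clustering: PCA over the HVG panel (50 PCs),
# KNN (k = 10) + Louvain across the 0.8-2.0 resolution sweep, few-DEG merge,
# cluster-vs-rest DEG table and a tSNE map (perplexity 10). Writes
# clusters, DEGs, PCA scores and tSNE coordinates under results/.

suppressPackageStartupMessages(library(senlineage))

logmat <- read_expression_matrix("results/logmat.tsv", "tsv", scale_tag = "log")
panel_df <- read.table("results/hvg_panel.tsv", header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)

cl <- cluster_cells(logmat, panel_df$gene, n_pcs = 50, k = 10, seed = 0)
a <- cl$assignment
message("chose resolution ", cl$resolution, " -> K = ", attr(a, "K"),
        " clusters of sizes ", paste(sort(table(as.integer(a)),
                                          decreasing = TRUE), collapse = " "))
v50 <- 100 * sum(cl$embedding$var_frac[1:50])
message(sprintf("top-50 PCs explain %.1f%% of panel variance", v50))

write.table(data.frame(cell = names(a), cluster = as.integer(a)),
            "results/clusters.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cl$degs[cl$degs$deg, ], "results/degs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(cell = rownames(cl$embedding$coords),
                       cl$embedding$coords, check.names = FALSE),
            "results/pca_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
if (requireNamespace("Rtsne", quietly = TRUE)) {
  y <- embed_2d(cl$embedding, perplexity = 10, seed = 0)
  write.table(data.frame(cell = rownames(y), y), "results/tsne.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
}
up <- cl$degs[cl$degs$deg & cl$degs$direction == "up", ]
message("upregulated DEGs per cluster: ",
        paste(names(table(up$cluster)), table(up$cluster), sep = ":",
              collapse = " "))
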