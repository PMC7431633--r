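#!/usr/bin/env Rscript
# Bulk integration: per-cluster pseudo-bulk averages, consecutively
# monotone genes along the PD6-PD11 passage series, the three-way
# expressed-gene overlap, and the joint PCA of bulk samples with cluster
# pseudo-bulks over their shared expressed genes.

suppressPackageStartupMessages(library(senlineage))

sc <- read_expression_matrix("results/data/matrix.tsv", "tsv")
bulk <- bulk_series(read_expression_matrix("results/data/bulk.tsv", "tsv"))
gene_sets <- read_gene_sets_gmt("results/data/genesets.gmt")
clusters <- read.table("results/clusters.tsv", header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
a <- structure(stats::setNames(clusters$cluster, clusters$cell),
               K = length(unique(clusters$cluster)), class = "ClusterAssignment")

sc_f <- filter_expressed_genes(filter_cells(sc, 2000), "sc")
bulk_f <- filter_expressed_genes(bulk, "bulk")

pb <- pseudobulk_average(sc_f, a)
write_expression_matrix(pb, "results/pseudobulk.tsv", "tsv")

mono <- select_monotone_genes(bulk_f)
message(length(mono$up), " consecutively upregulated and ", length(mono$down),
        " consecutively downregulated genes across PD6-PD11")
writeLines(mono$up, "results/monotone_up.txt")
writeLines(mono$down, "results/monotone_down.txt")

venn <- overlap_expressed_genes(sc_f$gene_ids, bulk_f$gene_ids,
                                gene_sets$senescence_core)
message("expressed-gene overlap (sc / bulk / senescence annotation): ",
        paste(names(venn), venn, sep = "=", collapse = " "))
write.table(data.frame(region = names(venn), count = as.integer(venn)),
            "results/venn.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

shared <- intersect(sc_f$gene_ids, bulk_f$gene_ids)
jp <- joint_pca_compare(bulk_f, pb, shared)
write.table(data.frame(column = rownames(jp$coords), type = jp$type,
                       jp$coords[, 1:5], check.names = FALSE),
            "results/joint_pca.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
pc1 <- jp$coords[, 1]
message(sprintf(
  "joint PCA: PC1 (%.0f%% var) separates platforms (bulk mean %.1f vs pseudo-bulk %.1f); PC2 carries the senescence axis",
  100 * jp$var_frac[1], mean(pc1[jp$type == "bulk"]),
  mean(pc1[jp$type == "pseudobulk"])))
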