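#!/usr/bin/env Rscript
# Regulon discovery: TF co-expression modules (Pearson r >= 0.3), pruned
# against the motif-ranking database (recovery AUC over the top 5% of each
# ranking, NES >= 3 over all motifs), scored per cell, and tested for
# lineage commitment (|Pearson r| > 0.3 between normalized activity and
# pseudotime on each lineage's retained cells).

suppressPackageStartupMessages(library(senlineage))

logmat <- read_expression_matrix("results/logmat.tsv", "tsv", scale_tag = "log")
tfs <- intersect(readLines("results/data/tfs.txt"), logmat$gene_ids)
db <- read_motif_rankings("results/data/motif_ranks.tsv",
                          "results/data/motif_annotation.tsv")
pt <- read.table("results/pseudotime.tsv", header = TRUE, sep = "\t",
                 stringsAsFactors = FALSE)
class(pt) <- c("PseudotimeAssignment", "data.frame")

modules <- build_coexpression_modules(logmat, tfs, r_min = 0.3)
message("co-expression modules: ",
        paste(names(modules), lengths(modules), sep = ":", collapse = " "))
regs <- prune_modules_with_motifs(modules, db, top_fraction = 0.05,
                                  nes_min = 3)
message(length(regs), " regulons survive motif pruning: ",
        paste(vapply(regs, function(r)
          sprintf("%s(%d targets, NES %.1f)", r$tf, length(r$targets),
                  max(r$nes)), character(1)), collapse = "  "))

scores <- score_regulons(logmat, regs, T = 3000, seed = 0)
commitment <- do.call(rbind, lapply(unique(pt$lineage), function(ln)
  lineage_committed_regulons(scores, pt, ln, r_thresh = 0.3)))
write.table(commitment, "results/commitment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(
  tf = vapply(regs, `[[`, "", "tf"),
  n_targets = vapply(regs, function(r) length(r$targets), 0),
  max_nes = vapply(regs, function(r) max(r$nes), 0),
  targets = vapply(regs, function(r) paste(r$targets, collapse = ","), "")),
  "results/regulons.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

com <- commitment[commitment$retained, ]
message("lineage-committed regulons: ",
        paste(sprintf("%s@%s r=%.2f", com$regulon, com$lineage, com$r),
              collapse = "  "))
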