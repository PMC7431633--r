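#!/usr/bin/env Rscript
# Generate the default synthetic replicative-senescence experiment: 175 cells
# x 10,000 genes in six states along three branching fates, a PD6-PD11 bulk
# series, program gene sets, a TF list, a motif-ranking database, and the
# ground truth. Writes everything as plain text under results/data/.

suppressPackageStartupMessages(library(senlineage))

seed <- 1
dataset <- generate_dataset(preset_config("mef175"), seed = seed)
write_dataset(dataset, "results/data")

tab <- table(dataset$truth$cluster)
message("cells per state: ", paste(names(tab), tab, sep = ":", collapse = " "))
message("lineages: ", paste(vapply(dataset$truth$lineages, paste,
                                   character(1), collapse = "-"),
                            collapse = "  "))
message("monotone truth: ", length(dataset$truth$monotone_up), " up, ",
        length(dataset$truth$monotone_down), " down")
message("wrote results/data (seed ", seed, ")")
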