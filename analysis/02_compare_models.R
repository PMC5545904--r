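#!/usr/bin/env Rscript
# Edge-level cross-species concordance: classify every human edge of the
# simulated pathway against the mouse model, stratified by molecular vs
# cellular level, and check recovery of the generating labels.

suppressPackageStartupMessages(library(crossbel))
dir.create("results", showWarnings = FALSE)

human <- load_edge_table("results/synthetic/human_model.tsv")
mouse <- load_edge_table("results/synthetic/mouse_model.tsv")
truth <- read.delim("results/synthetic/edge_truth.tsv")

cmp <- compare_models(human, mouse, orthology_map())
write.table(cmp$records, "results/concordance_records.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cmp$summary, "results/concordance_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

mrg <- merge(cmp$records[, c("human_triple", "category")], truth,
             by = "human_triple")
cat("classified", nrow(cmp$records), "human edges;",
    sum(mrg$category == mrg$label), "match the generating labels\n")
print(cmp$summary[cmp$summary$level != "all", ])
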