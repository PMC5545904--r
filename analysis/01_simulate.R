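#!/usr/bin/env Rscript
# Generate the labelled synthetic inputs used by the downstream steps:
# a paired human/mouse causal model with known per-edge concordance
# labels, and GEO2R-style DE call tables with known per-gene categories.

suppressPackageStartupMessages(library(crossbel))
dir.create("results/synthetic", recursive = TRUE, showWarnings = FALSE)

gp <- generate_model_pair(n_edges = 73, p_consistent = 0.27,
                          p_contradictory = 0.15, p_unique = 0.58,
                          cellular_fraction = 40 / 73, seed = 101)
write_edge_table(gp$human, "results/synthetic/human_model.tsv")
write_edge_table(gp$mouse, "results/synthetic/mouse_model.tsv")
write.table(gp$truth, "results/synthetic/edge_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("model pair: 73 human edges, labels",
    paste(names(gp$counts), gp$counts, sep = "=", collapse = ", "), "\n")

ex <- generate_expression_tables(counts = c(31, 14, 19, 17, 7, 12),
                                 seed = 102)
for (sp in c("human", "mouse"))
  for (acc in names(ex[[sp]]))
    write.table(ex[[sp]][[acc]],
                sprintf("results/synthetic/de_%s_%s.tsv", sp, acc),
                sep = "\t", quote = FALSE, row.names = FALSE)
write.table(ex$truth, "results/synthetic/gene_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("expression cohort: 100 genes across",
    length(ex$human), "human and", length(ex$mouse), "mouse datasets\n")
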