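#!/usr/bin/env Rscript
# Over-representation analysis of each celecoxib case-study model's gene
# list against the bundled neuroinflammation gene sets, then the
# shared / species-unique partition of significant sets.

suppressPackageStartupMessages(library(crossbel))

mods <- celecoxib_models()
sets <- read_gmt(neuroinflammation_gmt())
genes_of <- function(m)
  sort(unique(toupper(m$entities$id[m$entities$ns %in% c("HGNC", "MGI")])))
universe <- unique(c(unlist(sets), genes_of(mods$human),
                     genes_of(mods$mouse)))
res_h <- ora(genes_of(mods$human), sets, universe)
res_m <- ora(genes_of(mods$mouse), sets, universe)
write.table(res_h, "results/ora_human.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(res_m, "results/ora_mouse.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
part <- shared_unique_sets(res_h, res_m, q_threshold = 0.05)
cat("significant sets - shared:", length(part$shared),
    "| human-only:", length(part$unique_to_human),
    "| mouse-only:", length(part$unique_to_mouse), "\n")
print(res_h[, c("set", "overlap_k", "set_size_K", "p", "q")])
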