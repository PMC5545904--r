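#!/usr/bin/env Rscript
# Six-way cross-species expression concordance over the simulated
# GEO2R-style call tables.

suppressPackageStartupMessages(library(crossbel))

load_calls <- function(sp) {
  files <- list.files("results/synthetic",
                      pattern = paste0("^de_", sp, "_"), full.names = TRUE)
  do.call(rbind, lapply(files, function(f)
    load_de_table(f, sp, sub("\\.tsv$", "", sub(".*_", "", f)))))
}
ct <- concordance_table(load_calls("human"), load_calls("mouse"),
                        orthology_map(), alpha = 0.05)
write.table(ct, "results/expression_concordance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
s <- summarize_concordance(ct)
write.table(s$table, "results/expression_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("classified", s$denominator, "genes\n")
print(s$table)
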