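#!/usr/bin/env Rscript
# Celecoxib mode-of-action contrast: propagate the drug's inhibition of
# PTGS2 and PDPK1 through each species' model and compare predicted
# downstream effects.

suppressPackageStartupMessages(library(crossbel))

mods <- celecoxib_models()
act <- celecoxib_action()
res_h <- propagate(mods$human, act, max_len = 6)
res_m <- propagate(mods$mouse, act, max_len = 6)
write.table(res_h$nodes, "results/moa_human_nodes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res_m$nodes, "results/moa_mouse_nodes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(res_h$paths, "results/moa_human_paths.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

agreement <- compare_perturbation(res_h, res_m,
                                  neuroinflammation_orthology())
write.table(agreement, "results/moa_agreement.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("mouse model predicts: Il4", node_sign(res_m, "Il4"),
    "| Ins", node_sign(res_m, "Ins"),
    "| amyloid-beta", node_sign(res_m, "amyloid-beta"), "\n")
cat("human model predicts: MTOR", node_sign(res_h, "MTOR"),
    "| insulin resistance", node_sign(res_h, "insulin resistance"),
    "| amyloid-beta", node_sign(res_h, "amyloid-beta"), "\n")
cat("species disagree on:",
    paste(agreement$node[agreement$outcome == "disagree"],
          collapse = ", "), "\n")
print(agreement)
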