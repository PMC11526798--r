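#!/usr/bin/env Rscript
# Stagewise linear modelling: voom transform, baseline model (intercept +
# four stage-lfc coefficients), empirical-Bayes moderation and BH-adjusted
# moderated-F ranking. Writes the ranked table and prints the top genes.

source("analysis/common.R")

pip <- get_pipeline()
lin <- pip$linear

message(sum(lin$significant), " of ", nrow(lin),
        " genes significant in the linear model (adj p < 1e-5)")
message("top of the ranking (lfc per stage, regulation status):")
print(head(lin[, c("gene", "lfc_I", "lfc_II", "lfc_III", "lfc_IV",
                   "adj_p", "status")], 10), digits = 3)

truth <- load_truth()
top10 <- head(lin$gene, 10)
message("planted classes among the top 10: ",
        paste(truth$planted_class[match(top10, truth$gene_id)],
              collapse = ", "))

write_tsv(lin, file.path(res_dir("tables"), "linear_model.tsv"))
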