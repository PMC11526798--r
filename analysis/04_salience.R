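#!/usr/bin/env Rscript
# Stage salience: stage-vs-control and between-stage contrasts off the
# cell-means model, |lfc| > 2 stage-specificity, the four-pronged salience
# filter, pval_pdt, and the per-stage top-10 candidate tables.

source("analysis/common.R")

pip <- get_pipeline()
rec <- pip$salience
truth <- load_truth()

sal <- rec[rec$stage_salient, ]
message(nrow(sal), " stage-salient genes")
print(table(stage = sal$assigned_stage,
            planted = truth$planted_class[match(sal$gene, truth$gene_id)]))

top <- top_stage_table(rec, k = 10)
out <- res_dir("tables")
for (s in names(top)) {
  write_tsv(top[[s]][, c("gene", "assigned_stage", "max_abs_lfc",
                         "adj_p_vs_control", "pval_pdt", "stage_salient",
                         "in_top_k")],
            file.path(out, sprintf("top_stage_%s.tsv", s)))
}
write_tsv(rec, file.path(out, "salience_records.tsv"))
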