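#!/usr/bin/env Rscript
# Ingest the cohort files: parse barcodes into tumor/control classes, merge
# the clinical stage annotation (collapsing sub-stages to parents), drop
# NA-stage tumors and low-variance genes, and report the filter funnel.

source("analysis/common.R")

expr <- read_expression_matrix(file.path(cohort_dir(), "expression.tsv"))
clin <- read_clinical_table(file.path(cohort_dir(), "clinical.tsv"))
merged <- merge_and_annotate(expr, clin)
filtered <- apply_filters(merged)

print(filtered)

out <- res_dir("tables")
write_tsv(data.frame(sample = colnames(filtered$values),
                     class = as.character(filtered$sample_class),
                     stage = as.character(filtered$stage)),
          file.path(out, "sample_annotation.tsv"))
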