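#!/usr/bin/env Rscript
# Simulate the study cohort: a stage-annotated expression matrix with planted
# null, globally-DE, stage-salient, monotone and prognostic genes, plus
# proportional-hazards survival outcomes, written as firebrowse-style fixture
# files that the ingest drivers consume.

source("analysis/common.R")

cfg <- study_config()
ds <- generate_expression_dataset(cfg)
surv <- generate_survival_outcomes(ds$expr, ds$truth, cfg)

message("cohort: ", nrow(ds$expr$values), " genes x ",
        ncol(ds$expr$values), " samples")
print(table(planted = ds$truth$planted_class))
message(sum(surv$event), " deaths among ", nrow(surv), " tumor samples (",
        round(100 * (1 - mean(surv$event))), "% censored)")

paths <- write_fixture(ds$expr, ds$truth, cohort_dir(), surv = surv,
                       substages = TRUE)
for (p in paths) message("wrote ", p)
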