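# Shared plumbing for the analysis drivers: paths, the simulated cohort
# location, and a run-time cache of the modelling pipeline so the later
# drivers do not refit the same models.

library(stagewiseDE)

res_dir <- function(...) {
  d <- file.path("results", ...)
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

cohort_dir <- function() file.path("results", "cohort")

study_config <- function(seed = 20260930) {
  # Table-3-like group sizes (51 controls, 57/136/113/52 tumors) and effect
  # sizes at the generator defaults; ~1.2k genes keeps every driver fast.
  sim_config(seed = seed)
}

load_filtered <- function() {
  expr <- read_expression_matrix(file.path(cohort_dir(), "expression.tsv"))
  clin <- read_clinical_table(file.path(cohort_dir(), "clinical.tsv"))
  apply_filters(merge_and_annotate(expr, clin))
}

get_pipeline <- function() {
  cache <- file.path("results", "cache", "pipeline.rds")
  if (file.exists(cache)) return(readRDS(cache))
  res <- run_stagewise_pipeline(load_filtered())
  dir.create(dirname(cache), showWarnings = FALSE, recursive = TRUE)
  saveRDS(res, cache)
  res
}

load_truth <- function() {
  utils::read.delim(file.path(cohort_dir(), "truth.tsv"),
                    stringsAsFactors = FALSE)
}

load_survival <- function() {
  clin <- read_clinical_table(file.path(cohort_dir(), "clinical.tsv"))
  expr <- read_expression_matrix(file.path(cohort_dir(), "expression.tsv"))
  tum <- colnames(expr$values)[expr$sample_class == "tumor"]
  m <- match(sub("^((?:[^-]+-){2}[^-]+)-.*$", "\\1", tum), clin$barcode)
  data.frame(sample_id = tum, time = clin$os_time[m],
             event = clin$os_event[m], stringsAsFactors = FALSE)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path, " (", nrow(x), " rows)")
}
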