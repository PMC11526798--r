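# shared small synthetic configs; everything is generated in code at test time

small_cohort <- function(seed = 1, ...) {
  cfg <- sim_config(n_per_group = 30, n_null = 200, n_global_de = 10,
                    n_stage_salient = 8, n_monotone_up = 5,
                    n_monotone_down = 5, n_prognostic = 2, seed = seed, ...)
  c(generate_expression_dataset(cfg), list(config = cfg))
}

# a fake contrast_fit for unit tests of the salience logic
fake_contrast_fit <- function(lfc, p = NULL, adj_p = NULL) {
  if (is.null(p)) p <- matrix(1, nrow(lfc), ncol(lfc), dimnames = dimnames(lfc))
  if (is.null(adj_p)) {
    adj_p <- p
    for (j in seq_len(ncol(p))) adj_p[, j] <- stagewiseDE::adjust_bh(p[, j])
  }
  structure(list(efit = NULL, lfc = lfc, p = p, adj_p = adj_p),
            class = "contrast_fit")
}

group_means_oracle <- function(values, stages) {
  stages <- factor(as.character(stages),
                   levels = c("control", "I", "II", "III", "IV"))
  t(apply(values, 1, function(v) tapply(v, stages, mean)))
}
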