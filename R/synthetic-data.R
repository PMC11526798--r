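#' Simulation configuration for the synthetic cohort generator
#'
#' Bundles every knob of the synthetic stage-annotated cohort. The defaults
#' describe the study conditions the pipeline is aimed at: a colorectal-type
#' cohort with the stagewise class imbalance of the reference TCGA COADREAD
#' cohort (51 controls and 57/136/113/52 tumors in stages I-IV), expression on
#' the log2 RSEM scale with unit Gaussian noise, planted stage-salient genes
#' at |lfc| = 3 (comfortably past the |lfc| > 2 salience gate), monotone genes
#' with slope 0.8 log2 units per stage index, and prognostic genes acting on
#' the hazard with coefficient 0.5 per log2 unit.
#'
#' @param n_per_group samples per group; either one integer (used for all five
#'   groups) or a length-5 vector ordered (control, I, II, III, IV).
#' @param n_null,n_global_de,n_stage_salient,n_monotone_up,n_monotone_down,n_prognostic
#'   planted gene counts per class. Stage-salient genes are spread round-robin
#'   over the four stages.
#' @param baseline_mean baseline log2 expression.
#' @param noise_sd per-observation Gaussian noise sd (log2 units), > 0.
#' @param lfc_magnitude planted log2 fold change for global-DE and
#'   stage-salient genes (sign alternates gene to gene).
#' @param slope_magnitude planted slope (log2 units per stage index 0..4) for
#'   monotone genes.
#' @param cox_beta planted log-hazard coefficient per log2 expression unit for
#'   prognostic genes.
#' @param censoring_rate fraction of tumor samples administratively censored,
#'   in \[0, 1\].
#' @param baseline_hazard exponential baseline hazard (> 0, per day).
#' @param seed integer seed governing all randomness of the generator.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = c(51, 57, 136, 113, 52),
                       n_null = 800, n_global_de = 50, n_stage_salient = 40,
                       n_monotone_up = 30, n_monotone_down = 30,
                       n_prognostic = 10,
                       baseline_mean = 8, noise_sd = 1,
                       lfc_magnitude = 3, slope_magnitude = 0.8,
                       cox_beta = 0.5, censoring_rate = 0.3,
                       baseline_hazard = 5e-4, seed = 1L) {
  if (length(n_per_group) == 1) n_per_group <- rep(n_per_group, 5)
  if (length(n_per_group) != 5 || any(n_per_group < 0))
    stop("n_per_group must be 1 or 5 nonnegative counts (control, I..IV)")
  names(n_per_group) <- stage_levels()
  counts <- c(n_null = n_null, n_global_de = n_global_de,
              n_stage_salient = n_stage_salient,
              n_monotone_up = n_monotone_up, n_monotone_down = n_monotone_down,
              n_prognostic = n_prognostic)
  if (any(counts < 0)) stop("planted gene counts must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (censoring_rate < 0 || censoring_rate > 1)
    stop("censoring_rate must be in [0, 1]")
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (n_stage_salient > 0 && any(n_per_group == 0))
    stop("stage-salient genes require samples in every group")
  structure(
    list(n_per_group = n_per_group, n_null = n_null,
         n_global_de = n_global_de, n_stage_salient = n_stage_salient,
         n_monotone_up = n_monotone_up, n_monotone_down = n_monotone_down,
         n_prognostic = n_prognostic, baseline_mean = baseline_mean,
         noise_sd = noise_sd, lfc_magnitude = lfc_magnitude,
         slope_magnitude = slope_magnitude, cox_beta = cox_beta,
         censoring_rate = censoring_rate, baseline_hazard = baseline_hazard,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# per-gene truth rows for one planted class
truth_rows <- function(ids, class, target_stage, lfc, slope, beta) {
  if (length(ids) == 0) return(NULL)
  data.frame(gene_id = ids, planted_class = class,
             target_stage = target_stage,
             lfc_I = lfc[, 1], lfc_II = lfc[, 2],
             lfc_III = lfc[, 3], lfc_IV = lfc[, 4],
             planted_slope = slope, cox_beta = beta,
             stringsAsFactors = FALSE)
}

#' Generate a stage-annotated expression dataset with planted ground truth
#'
#' Draws a log2-scale matrix over five groups (control + stages I-IV).
#' Null genes share one group-independent mean; global-DE genes are shifted by
#' `lfc_magnitude` in all four tumor stages; stage-salient genes are shifted
#' only in their target stage (so the target stage strictly dominates);
#' monotone genes follow mean = baseline + slope * X with X = 0..4; prognostic
#' genes are expression-null but flagged to drive the survival generator.
#' Signs of planted fold changes alternate gene to gene so both up- and
#' down-regulated markers exist.
#'
#' @param config a [sim_config()].
#' @return list with `expr` (an [annotated_expression()]) and `truth` (the
#'   per-gene truth table; one row per generated gene).
#' @export
generate_expression_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  npg <- config$n_per_group
  stage <- factor(rep(stage_levels(), npg), levels = stage_levels())
  n <- length(stage)
  cls <- ifelse(stage == "control", "control", "tumor")
  sample_ids <- synth_barcodes(cls)

  alt_sign <- function(k) if (k == 0) numeric(0) else rep_len(c(1, -1), k)
  zeros <- function(k) matrix(0, k, 4)

  # planted per-stage lfc matrices (columns I..IV)
  lfc_null <- zeros(config$n_null)
  lfc_glob <- alt_sign(config$n_global_de) * config$lfc_magnitude
  lfc_glob <- matrix(lfc_glob, ncol = 4, nrow = config$n_global_de)
  sal_stage <- rep_len(tumor_stages(), config$n_stage_salient)
  lfc_sal <- zeros(config$n_stage_salient)
  if (config$n_stage_salient > 0) {
    s_idx <- match(sal_stage, tumor_stages())
    lfc_sal[cbind(seq_along(s_idx), s_idx)] <-
      alt_sign(config$n_stage_salient) * config$lfc_magnitude
  }
  slope_up <- rep(config$slope_magnitude, config$n_monotone_up)
  slope_dn <- rep(-config$slope_magnitude, config$n_monotone_down)
  X <- c(control = 0, I = 1, II = 2, III = 3, IV = 4)
  lfc_up <- outer(slope_up, X[tumor_stages()])
  lfc_dn <- outer(slope_dn, X[tumor_stages()])
  lfc_prog <- zeros(config$n_prognostic)

  ids <- function(prefix, k) if (k == 0) character(0) else
    sprintf("%s%04d", prefix, seq_len(k))
  truth <- rbind(
    truth_rows(ids("NULLG", config$n_null), "null", NA, lfc_null, 0, 0),
    truth_rows(ids("GLOBL", config$n_global_de), "global_de", NA, lfc_glob, 0, 0),
    truth_rows(ids("SALNT", config$n_stage_salient), "stage_salient",
               sal_stage, lfc_sal, 0, 0),
    truth_rows(ids("MONUP", config$n_monotone_up), "monotone_up", NA,
               lfc_up, slope_up, 0),
    truth_rows(ids("MONDN", config$n_monotone_down), "monotone_down", NA,
               lfc_dn, slope_dn, 0),
    truth_rows(ids("PROGN", config$n_prognostic), "prognostic", NA,
               lfc_prog, 0, config$cox_beta)
  )
  if (is.null(truth) || nrow(truth) == 0) stop("no genes requested")

  lfc_all <- as.matrix(truth[, c("lfc_I", "lfc_II", "lfc_III", "lfc_IV")])
  shift <- cbind(control = 0, lfc_all)[, as.integer(stage), drop = FALSE]
  means <- config$baseline_mean + shift
  values <- means + matrix(rnorm(nrow(truth) * n, sd = config$noise_sd),
                           nrow(truth), n)
  values <- pmax(values, 0)  # log2 RSEM values are nonnegative
  dimnames(values) <- list(truth$gene_id, sample_ids)
  expr <- annotated_expression(values, cls, as.character(stage))
  list(expr = expr, truth = truth)
}

synth_barcodes <- function(cls) {
  type <- ifelse(cls == "control", "11A", "01A")
  sprintf("TCGA-SM-%04d-%s", seq_along(cls), type)
}

#' Simulate survival outcomes under a proportional-hazards model
#'
#' Event times for tumor samples are exponential with hazard
#' `baseline_hazard * exp(sum(cox_beta * (expression - baseline_mean)))` over
#' the planted prognostic genes, which embeds the linear risk-score structure
#' the prognostic stage estimates; centring at the baseline mean keeps
#' `baseline_hazard` interpretable as the hazard of an average patient (Cox
#' estimates are invariant to the shift). Censoring is administrative: records
#' with event
#' time at or above the empirical `(1 - censoring_rate)` quantile of the
#' simulated times are censored there.
#'
#' @param expr an [annotated_expression()] from [generate_expression_dataset()].
#' @param truth its truth table.
#' @param config the same [sim_config()].
#' @return data.frame (`survival_table`): `sample_id`, `time` (days), `event`
#'   (1 = death observed), one row per tumor sample.
#' @export
generate_survival_outcomes <- function(expr, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  prog <- truth$gene_id[truth$cox_beta != 0]
  tum <- which(expr$sample_class == "tumor")
  if (length(tum) == 0) stop("no tumor samples to assign outcomes to")
  set.seed(config$seed + 1L)
  lp <- if (length(prog))
    colSums((expr$values[prog, tum, drop = FALSE] - config$baseline_mean) *
              truth$cox_beta[match(prog, truth$gene_id)])
  else rep(0, length(tum))
  rate <- config$baseline_hazard * exp(lp)
  t_event <- stats::rexp(length(tum), rate = rate)
  if (config$censoring_rate == 0) {
    time <- t_event; event <- rep(1L, length(tum))
  } else {
    cutoff <- stats::quantile(t_event, probs = 1 - config$censoring_rate,
                              names = FALSE, type = 1)
    event <- as.integer(t_event < cutoff)
    time <- pmin(t_event, cutoff)
  }
  data.frame(sample_id = colnames(expr$values)[tum], time = time,
             event = event, stringsAsFactors = FALSE)
}

#' Write a synthetic cohort as firebrowse-style fixture files
#'
#' Emits three tab-separated files under `dir`: `expression.tsv` in the
#' firebrowse dialect (a "Hybridization REF" header row with full sample
#' barcodes, a second annotation row, then `SYMBOL|ENTREZ` gene rows),
#' `clinical.tsv` with one row per tumor patient (lowercase attribute names,
#' `pathologic_stage` spelled as e.g. "stage ii", optionally with sub-stage
#' letters), and `truth.tsv` with the planted ground truth. The files
#' round-trip losslessly through the ingest module.
#'
#' @param expr an [annotated_expression()].
#' @param truth its truth table.
#' @param dir output directory (created if needed).
#' @param surv optional survival table to populate `os_time`/`os_event`.
#' @param substages if `TRUE`, tumor stages are written with cycling sub-stage
#'   letters ("stage iia", ...) to exercise the collapse rule.
#' @return (invisibly) named character vector of the three file paths.
#' @export
write_fixture <- function(expr, truth, dir, surv = NULL, substages = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "truth.tsv"))

  ids <- colnames(expr$values)
  composite <- paste0(rownames(expr$values), "|", seq_len(nrow(expr$values)))
  con <- file(paths[["expression"]], "w")
  on.exit(close(con))
  writeLines(paste(c("Hybridization REF", ids), collapse = "\t"), con)
  writeLines(paste(c("gene", rep("normalized_count", length(ids))),
                   collapse = "\t"), con)
  if (nrow(expr$values) > 0) {
    body <- apply(expr$values, 1, function(v)
      paste(sprintf("%.6f", v), collapse = "\t"))
    writeLines(paste(composite, body, sep = "\t"), con)
  }
  close(con); on.exit()

  tum <- expr$sample_class == "tumor"
  patient <- sub("^((?:[^-]+-){2}[^-]+)-.*$", "\\1", ids[tum])
  stg <- tolower(as.character(expr$stage[tum]))
  token <- ifelse(is.na(stg), "NA", paste0("stage ", stg))
  if (substages) {
    letters3 <- rep_len(c("a", "b", "c"), sum(tum))
    token <- ifelse(is.na(stg), "NA", paste0("stage ", stg, letters3))
  }
  clin <- data.frame(bcr_patient_barcode = patient,
                     pathologic_stage = token,
                     os_time = NA_real_, os_event = NA_integer_,
                     stringsAsFactors = FALSE)
  if (!is.null(surv)) {
    m <- match(ids[tum], surv$sample_id)
    clin$os_time <- surv$time[m]
    clin$os_event <- surv$event[m]
  }
  utils::write.table(clin, paths[["clinical"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
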