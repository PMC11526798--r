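#' Run the stagewise biomarker pipeline on an annotated expression object
#'
#' Convenience driver chaining the modelling stages on a filtered
#' [annotated_expression()]: antilog to pseudo-counts, voom transform,
#' baseline and cell-means moderated fits, stage-vs-control and between-stage
#' contrasts, stage-specificity assignment and the four-pronged salience
#' filter, the numeric-stage monotone analysis, and the
#' progression-significant intersection.
#'
#' @param expr a filtered [annotated_expression()] with no NA stages.
#' @param lfc_threshold stage-specificity |lfc| cutoff (default 2).
#' @param alpha_control criterion (i) cutoff on the adjusted stage-vs-control
#'   p (default 0.001).
#' @param alpha_between criteria (ii)-(iv) cutoff on raw between-stage p
#'   (default 0.05).
#' @param alpha_linear significance cutoff for the baseline linear model
#'   (default 1e-5).
#' @param alpha_meg significance cutoff for monotone genes (default 0.05).
#' @return list with `vr` (voom `EList`), `linear` (ranked linear table),
#'   `salience` (salience records), `monotone` (monotone records),
#'   `progression` (progression-significant table), `cfit_control`,
#'   `cfit_between`.
#' @export
run_stagewise_pipeline <- function(expr, lfc_threshold = 2,
                                   alpha_control = 0.001,
                                   alpha_between = 0.05,
                                   alpha_linear = 1e-5,
                                   alpha_meg = 0.05) {
  stopifnot(inherits(expr, "annotated_expression"))
  if (anyNA(expr$stage)) stop("run apply_filters() first: NA stages present")
  stages <- as.character(expr$stage)
  counts <- to_pseudocounts(expr)

  design_cm <- build_design(stages, "cellmeans")
  vr <- voom_transform(counts, design_cm)

  # baseline model: stagewise lfc + moderated F ranking
  design_bl <- build_design(stages, "baseline")
  mfit_bl <- ebayes_moderate(fit_gene_models(vr, design_bl))
  linear <- summarize_linear_top(mfit_bl, alpha = alpha_linear)

  # contrasts off the cell-means model
  fit_cm <- fit_gene_models(vr, design_cm)
  cfit_control <- apply_contrasts(fit_cm, make_contrast_matrix("stage_vs_control"))
  cfit_between <- apply_contrasts(fit_cm, make_contrast_matrix("between_stages"))
  records <- assign_stage_specificity(cfit_control, lfc_threshold)
  records <- salience_filter(records, cfit_between,
                             alpha_control = alpha_control,
                             alpha_between = alpha_between)

  # monotone analysis on the same voom matrix
  numeric_fit <- fit_numeric_model(vr, stages)
  gm <- group_mean_matrix(vr, stages)
  monotone <- select_significant_megs(numeric_fit, gm, alpha = alpha_meg)
  progression <- intersect_progression(monotone, records)

  list(vr = vr, linear = linear, salience = records, monotone = monotone,
       progression = progression,
       cfit_control = cfit_control, cfit_between = cfit_between)
}
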