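#' Fit the numeric-stage model per gene
#'
#' Treats stage as a numeric covariate X in (0,1,2,3,4) for
#' (control, I..IV) and fits y = a*X + b per gene by weighted least squares
#' with the voom weights; the slope p-value is the moderated t-statistic
#' p-value from the same empirical-Bayes machinery, BH-adjusted across genes.
#'
#' @param vr a `limma::EList` from [voom_transform()] (or a plain matrix for
#'   equal weights).
#' @param stages per-sample stage labels.
#' @return data.frame: `gene`, `slope`, `intercept`, `p`, `adj_p`.
#' @export
fit_numeric_model <- function(vr, stages) {
  X <- stage_index(stages)
  if (length(unique(X)) < 2)
    stop("numeric-stage model needs at least 2 distinct stage values")
  design <- cbind(intercept = 1, X = X)
  fit <- limma::lmFit(vr, design)
  efit <- limma::eBayes(fit)
  data.frame(gene = rownames(efit$coefficients),
             slope = efit$coefficients[, "X"],
             intercept = efit$coefficients[, "intercept"],
             p = efit$p.value[, "X"],
             adj_p = adjust_bh(efit$p.value[, "X"]),
             stringsAsFactors = FALSE, row.names = NULL)
}

stage_index <- function(stages) {
  stages <- as.character(stages)
  bad <- !stages %in% stage_levels()
  if (any(bad)) stop("unknown stage label(s): ",
                     paste(unique(stages[bad]), collapse = ", "))
  c(control = 0, I = 1, II = 2, III = 3, IV = 4)[stages]
}

#' Detect strict monotone ordering of five group means
#'
#' `"up"` iff the means are strictly increasing over
#' control < I < II < III < IV, `"down"` iff strictly decreasing, otherwise
#' `"none"`. Comparisons are strict with no tolerance: any tie breaks
#' monotonicity.
#'
#' @param group_means numeric vector of 5 finite means, ordered
#'   (control, I, II, III, IV).
#' @return one of `"up"`, `"down"`, `"none"`.
#' @export
detect_monotone_direction <- function(group_means) {
  if (length(group_means) != 5 || anyNA(group_means) ||
      any(!is.finite(group_means)))
    stop("group_means must be 5 finite values (control, I..IV)")
  d <- diff(group_means)
  if (all(d > 0)) "up" else if (all(d < 0)) "down" else "none"
}

#' Per-group mean expression matrix
#'
#' Row = gene, column = group (control, I..IV), computed on the (voom logcpm)
#' matrix the models see.
#'
#' @param vr a `limma::EList` or matrix.
#' @param stages per-sample stage labels.
#' @return genes x 5 matrix of group means.
#' @export
group_mean_matrix <- function(vr, stages) {
  E <- if (is.matrix(vr)) vr else vr$E
  stages <- factor(as.character(stages), levels = stage_levels())
  sapply(stage_levels(), function(s)
    rowMeans(E[, stages == s, drop = FALSE]))
}

#' Select monotonically expressed genes (MEGs)
#'
#' Classifies each gene's direction from its five group means (strict
#' ordering, [detect_monotone_direction()]), merges the up and down sets into
#' the MEG set, and flags the significant subset at `adj_p < alpha` from the
#' numeric-stage model.
#'
#' @param numeric_fit data.frame from [fit_numeric_model()].
#' @param group_means genes x 5 matrix from [group_mean_matrix()].
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return monotone records: `numeric_fit` plus `direction`, `meg`,
#'   `significant_meg`.
#' @export
select_significant_megs <- function(numeric_fit, group_means, alpha = 0.05) {
  gm <- group_means[numeric_fit$gene, , drop = FALSE]
  direction <- apply(gm, 1, detect_monotone_direction)
  rec <- numeric_fit
  rec$direction <- unname(direction)
  rec$meg <- rec$direction != "none"
  rec$significant_meg <- rec$meg & rec$adj_p < alpha
  message(sprintf(
    "MEGs: %d (%d up, %d down); significant at adj p < %g: %d",
    sum(rec$meg), sum(rec$direction == "up"), sum(rec$direction == "down"),
    alpha, sum(rec$significant_meg)))
  rec
}

#' Intersect significant MEGs with stage-salient genes
#'
#' Progression-significant genes are both significant MEGs and stage-salient.
#' The table carries the salient stage, the monotone direction as UP/DOWN
#' status, and the numeric-model adjusted p, sorted with upregulated genes
#' first and by adjusted p within each block.
#'
#' @param meg_records records from [select_significant_megs()].
#' @param salient_records records from [salience_filter()].
#' @return data.frame: `gene`, `stage`, `status`, `adj_p`.
#' @export
intersect_progression <- function(meg_records, salient_records) {
  if (!any(meg_records$gene %in% salient_records$gene))
    stop("MEG and salience records share no genes: disjoint universes")
  sal <- salient_records[salient_records$stage_salient, , drop = FALSE]
  meg <- meg_records[meg_records$significant_meg, , drop = FALSE]
  common <- intersect(meg$gene, sal$gene)
  out <- data.frame(
    gene = common,
    stage = sal$assigned_stage[match(common, sal$gene)],
    status = toupper(meg$direction[match(common, meg$gene)]),
    adj_p = meg$adj_p[match(common, meg$gene)],
    stringsAsFactors = FALSE)
  out <- out[order(factor(out$status, levels = c("UP", "DOWN")),
                   out$adj_p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes both in the linear-model top list and significantly monotone
#'
#' The feature-space component joining the two trend views: significant MEGs
#' that also sit among the top `top_n` genes of the baseline linear model by
#' adjusted F p-value.
#'
#' @param linear_table ranked table from [summarize_linear_top()].
#' @param meg_records records from [select_significant_megs()].
#' @param top_n how deep into the linear ranking to look (default 200).
#' @return character vector of gene symbols.
#' @export
linear_monotone_overlap <- function(linear_table, meg_records, top_n = 200) {
  top <- utils::head(linear_table$gene, top_n)
  intersect(top, meg_records$gene[meg_records$significant_meg])
}
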