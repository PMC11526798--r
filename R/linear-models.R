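#' Build a stagewise design matrix
#'
#' Two layouts are supported. `baseline`: an all-ones intercept column
#' (baseline expression in controls) plus four stage indicator columns, so the
#' stage coefficients are log fold changes relative to control. `cellmeans`:
#' five disjoint group indicator columns (control, I..IV) and no intercept, so
#' each coefficient is that group's mean — the layout used for contrasts.
#' Column order is fixed as (intercept, I..IV) or (control, I..IV); absent
#' stages yield all-zero columns which the fit rejects as rank-deficient.
#'
#' @param stages per-sample stage labels in `c("control","I","II","III","IV")`.
#' @param mode `"baseline"` or `"cellmeans"`.
#' @return numeric design matrix (samples x coefficients) with a `mode`
#'   attribute.
#' @export
build_design <- function(stages, mode = c("baseline", "cellmeans")) {
  mode <- match.arg(mode)
  stages <- as.character(stages)
  bad <- !stages %in% stage_levels()
  if (length(stages) == 0 || any(bad))
    stop("unknown stage label(s): ",
         paste(unique(stages[bad]), collapse = ", "))
  ind <- sapply(stage_levels(), function(s) as.numeric(stages == s))
  ind <- matrix(ind, nrow = length(stages),
                dimnames = list(NULL, stage_levels()))
  design <- switch(mode,
    baseline = cbind(intercept = 1, ind[, tumor_stages(), drop = FALSE]),
    cellmeans = ind
  )
  attr(design, "mode") <- mode
  design
}

#' Fit per-gene weighted least-squares models
#'
#' Fits the stagewise linear model to every gene by weighted least squares
#' with the voom precision weights (via `limma::lmFit`), giving per-gene
#' coefficients, unscaled standard errors, residual variance and residual
#' degrees of freedom. Rank-deficient designs are rejected with the offending
#' columns named.
#'
#' @param vr a `limma::EList` from [voom_transform()], or a plain log-scale
#'   matrix (equal weights).
#' @param design a design matrix from [build_design()].
#' @return a `limma::MArrayLM` fit carrying the design's `mode` attribute.
#' @export
fit_gene_models <- function(vr, design) {
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dropped <- colnames(design)[qr_d$pivot[-seq_len(qr_d$rank)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  fit <- limma::lmFit(vr, design)
  attr(fit, "mode") <- attr(design, "mode")
  fit
}

#' Empirical-Bayes moderation of per-gene statistics
#'
#' Shrinks per-gene residual variances toward a shared prior estimated by the
#' moments method on log variances (trigamma inversion), yielding moderated
#' t-statistics on `d0 + df` degrees of freedom and a moderated F over the
#' stage coefficients (`limma::eBayes`). In baseline mode the F statistic
#' spans the four stage log-fold-change coefficients, excluding the intercept;
#' in cellmeans mode it spans all five group means. BH-adjusted F p-values are
#' attached.
#'
#' @param fit an `MArrayLM` from [fit_gene_models()].
#' @return object of class `moderated_fit`: list with `efit` (the moderated
#'   `MArrayLM`), `mode`, `d0` (prior df), `s0_2` (prior variance), and the
#'   stage-coefficient `F`, `F_p`, `F_adj_p` vectors.
#' @export
ebayes_moderate <- function(fit) {
  if (nrow(fit$coefficients) < 2)
    stop("moderation needs at least 2 genes with positive residual df")
  mode <- attr(fit, "mode")
  if (all(fit$sigma == 0)) {
    warning("all residual variances are zero; prior df is infinite and ",
            "posterior variance collapses to the prior variance",
            call. = FALSE)
    fit$sigma <- fit$sigma + 1e-15  # keep eBayes defined in the limit
  }
  efit <- limma::eBayes(fit)
  stage_cols <- if (identical(mode, "baseline"))
    which(colnames(fit$coefficients) != "intercept")
  else seq_len(ncol(fit$coefficients))
  sub <- limma::eBayes(fit[, stage_cols])
  structure(
    list(efit = efit, mode = mode,
         d0 = efit$df.prior, s0_2 = efit$s2.prior,
         s2_post = efit$s2.post,
         F = sub$F, F_p = sub$F.p.value,
         F_adj_p = adjust_bh(sub$F.p.value)),
    class = "moderated_fit"
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates the inputs and applies the BH step-up procedure
#' (`stats::p.adjust`). `NA` values propagate without affecting the ranks of
#' the rest.
#'
#' @param pvals numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return adjusted p-values, capped at 1.
#' @export
adjust_bh <- function(pvals) {
  ok <- is.na(pvals) | (pvals >= 0 & pvals <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Ranked summary of the baseline linear model
#'
#' Ranks genes by BH-adjusted moderated-F p-value (ties broken by max |lfc|
#' descending, then gene id) and labels regulation status: UP when all four
#' stage coefficients are positive, DOWN when all negative, MIXED otherwise.
#'
#' @param mfit a baseline-mode [ebayes_moderate()] result.
#' @param alpha significance cutoff on the adjusted F p-value.
#' @return data.frame: `gene`, `lfc_I`..`lfc_IV`, `F`, `p`, `adj_p`,
#'   `status`, `significant`, sorted by rank.
#' @export
summarize_linear_top <- function(mfit, alpha = 1e-5) {
  stopifnot(inherits(mfit, "moderated_fit"))
  if (!identical(mfit$mode, "baseline"))
    stop("summarize_linear_top expects a baseline-mode fit")
  beta <- mfit$efit$coefficients
  lfc <- beta[, tumor_stages(), drop = FALSE]
  status <- ifelse(rowSums(lfc > 0) == 4, "UP",
                   ifelse(rowSums(lfc < 0) == 4, "DOWN", "MIXED"))
  out <- data.frame(gene = rownames(beta),
                    lfc_I = lfc[, "I"], lfc_II = lfc[, "II"],
                    lfc_III = lfc[, "III"], lfc_IV = lfc[, "IV"],
                    F = mfit$F, p = mfit$F_p, adj_p = mfit$F_adj_p,
                    status = status,
                    significant = mfit$F_adj_p < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  max_lfc <- apply(abs(lfc), 1, max)
  out[order(out$adj_p, -max_lfc, out$gene), , drop = FALSE]
}
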