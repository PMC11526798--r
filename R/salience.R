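#' Contrast matrices for stagewise comparisons
#'
#' Literal contrast matrices over the cell-means coefficients
#' (control, I..IV). `stage_vs_control` has one column per stage with -1 on
#' the control row and +1 on the stage row. `between_stages` has the six
#' ordered stage pairs (I,II), (I,III), (II,III), (I,IV), (II,IV), (III,IV)
#' with -1 on the first-listed stage and +1 on the second; the control row is
#' zero. Every column sums to zero.
#'
#' @param kind `"stage_vs_control"` or `"between_stages"`.
#' @return numeric matrix, rows (control, I..IV), named columns.
#' @export
make_contrast_matrix <- function(kind = c("stage_vs_control",
                                          "between_stages")) {
  kind <- match.arg(kind)
  rows <- stage_levels()
  if (kind == "stage_vs_control") {
    C <- matrix(0, 5, 4, dimnames = list(rows, tumor_stages()))
    C["control", ] <- -1
    for (s in tumor_stages()) C[s, s] <- 1
  } else {
    pairs <- list(c("I", "II"), c("I", "III"), c("II", "III"),
                  c("I", "IV"), c("II", "IV"), c("III", "IV"))
    C <- matrix(0, 5, 6,
                dimnames = list(rows, vapply(pairs, paste, "", collapse = "-")))
    for (j in seq_along(pairs)) {
      C[pairs[[j]][1], j] <- -1
      C[pairs[[j]][2], j] <- 1
    }
  }
  C
}

# between-stage columns involving a given stage, in I<II<III<IV pair order
between_columns_for_stage <- function(stage) {
  cn <- colnames(make_contrast_matrix("between_stages"))
  cn[vapply(strsplit(cn, "-", fixed = TRUE),
            function(p) stage %in% p, logical(1))]
}

#' Apply a contrast matrix to a cell-means fit
#'
#' Maps coefficients and unscaled standard errors through the contrast
#' (`limma::contrasts.fit`, which propagates the coefficient covariance),
#' re-moderates on the contrast scale, and BH-adjusts each contrast column
#' across genes.
#'
#' @param fit a cellmeans-mode fit from [fit_gene_models()], or a
#'   [ebayes_moderate()] result wrapping one.
#' @param C a contrast matrix from [make_contrast_matrix()].
#' @return object of class `contrast_fit`: list with `efit` (moderated
#'   contrast `MArrayLM`), `lfc` (gene x contrast estimates), `p` (raw
#'   moderated p-values), `adj_p` (BH per column).
#' @export
apply_contrasts <- function(fit, C) {
  if (inherits(fit, "moderated_fit")) {
    if (!identical(fit$mode, "cellmeans"))
      stop("contrasts require a cellmeans-mode fit")
    fit <- fit$efit
  }
  if (nrow(C) != ncol(fit$coefficients))
    stop("contrast matrix rows must match the fit's coefficients")
  cfit <- limma::contrasts.fit(fit, C)
  # the lods prior is unused here and degenerates on all-zero contrasts
  ecfit <- withCallingHandlers(
    limma::eBayes(cfit),
    warning = function(w) {
      if (grepl("var.prior", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  p <- ecfit$p.value
  zero_cols <- colSums(C != 0) == 0   # a zero contrast estimates 0 with p = 1
  p[, zero_cols] <- 1
  adj_p <- p
  for (j in seq_len(ncol(p))) adj_p[, j] <- adjust_bh(p[, j])
  structure(
    list(efit = ecfit,
         lfc = ecfit$coefficients,
         p = p,
         adj_p = adj_p),
    class = "contrast_fit"
  )
}

#' Assign stage specificity by maximal |lfc|
#'
#' A gene is stage-specific when its largest absolute stage-vs-control log
#' fold change exceeds `lfc_threshold` (strict); it is assigned to the argmax
#' stage (earliest stage on exact ties). Genes below threshold in every stage
#' get no assigned stage.
#'
#' @param cfit a stage-vs-control [apply_contrasts()] result.
#' @param lfc_threshold strict |lfc| cutoff (default 2 log2 units).
#' @return data.frame of salience records: `gene`, `lfc_I`..`lfc_IV`,
#'   `assigned_stage`, `max_abs_lfc`, `adj_p_vs_control` (of the assigned
#'   stage), `stage_specific`.
#' @export
assign_stage_specificity <- function(cfit, lfc_threshold = 2.0) {
  stopifnot(inherits(cfit, "contrast_fit"))
  lfc <- cfit$lfc[, tumor_stages(), drop = FALSE]
  max_abs <- apply(abs(lfc), 1, max)
  arg <- apply(abs(lfc), 1, which.max)  # which.max: earliest on ties
  specific <- max_abs > lfc_threshold
  assigned <- ifelse(specific, tumor_stages()[arg], NA)
  adj_sel <- cfit$adj_p[cbind(seq_len(nrow(lfc)), arg)]
  rec <- data.frame(gene = rownames(lfc),
                    lfc_I = lfc[, "I"], lfc_II = lfc[, "II"],
                    lfc_III = lfc[, "III"], lfc_IV = lfc[, "IV"],
                    assigned_stage = assigned,
                    max_abs_lfc = max_abs,
                    adj_p_vs_control = ifelse(specific, adj_sel, NA),
                    stage_specific = specific,
                    stringsAsFactors = FALSE, row.names = NULL)
  message(sprintf(
    "stage specificity: %d of %d genes pass |lfc| > %g (%d eliminated); %s",
    sum(specific), nrow(rec), lfc_threshold, sum(!specific),
    paste(sprintf("%s: %d", tumor_stages(),
                  table(factor(assigned, tumor_stages()))), collapse = ", ")))
  rec
}

#' Product of between-stage p-values (pval_pdt)
#'
#' For each stage-specific gene, the product of the three raw between-stage
#' contrast p-values that involve its assigned stage (e.g. for a stage-I gene:
#' I-vs-II times I-vs-III times I-vs-IV). Used to rank candidates when strict
#' salience is sparse; at the conventional 0.05 per-contrast level the product
#' equals 1.25e-4.
#'
#' @param records salience records from [assign_stage_specificity()].
#' @param cfit_between a between-stages [apply_contrasts()] result.
#' @return numeric vector in (0, 1\], `NA` for genes with no assigned stage.
#' @export
compute_pval_pdt <- function(records, cfit_between) {
  stopifnot(inherits(cfit_between, "contrast_fit"))
  p <- cfit_between$p
  vapply(seq_len(nrow(records)), function(i) {
    s <- records$assigned_stage[i]
    if (is.na(s)) return(NA_real_)
    cols <- between_columns_for_stage(s)
    pv <- p[records$gene[i], cols]
    if (anyNA(pv)) stop("missing between-stage p-value for gene ",
                        records$gene[i])
    prod(pv)
  }, numeric(1))
}

#' Four-pronged stage-salience filter
#'
#' A stage-specific gene is stage-salient for its assigned stage iff
#' (i) the BH-adjusted stage-vs-control p-value of that stage is below
#' `alpha_control`, and (ii)-(iv) the three raw between-stage contrast
#' p-values involving that stage are all below `alpha_between`. Also attaches
#' the three between-stage p-values and the pval_pdt for every stage-specific
#' gene (salient or not), so the fallback ranking is total.
#'
#' @param records salience records from [assign_stage_specificity()].
#' @param cfit_between a between-stages [apply_contrasts()] result.
#' @param alpha_control cutoff for criterion (i) (adjusted; default 0.001).
#' @param alpha_between cutoff for criteria (ii)-(iv) (raw; default 0.05).
#' @param between_adjusted use BH-adjusted between-stage p-values instead of
#'   raw ones for (ii)-(iv) (default `FALSE`, matching the criteria as
#'   stated).
#' @return the records with columns `p_between_1..3`, `pval_pdt`,
#'   `stage_salient` added.
#' @export
salience_filter <- function(records, cfit_between,
                            alpha_control = 0.001, alpha_between = 0.05,
                            between_adjusted = FALSE) {
  stopifnot(inherits(cfit_between, "contrast_fit"))
  pmat <- if (between_adjusted) cfit_between$adj_p else cfit_between$p
  pb <- matrix(NA_real_, nrow(records), 3,
               dimnames = list(NULL, paste0("p_between_", 1:3)))
  for (i in which(!is.na(records$assigned_stage))) {
    cols <- between_columns_for_stage(records$assigned_stage[i])
    pb[i, ] <- pmat[records$gene[i], cols]
  }
  records$p_between_1 <- pb[, 1]
  records$p_between_2 <- pb[, 2]
  records$p_between_3 <- pb[, 3]
  records$pval_pdt <- compute_pval_pdt(records, cfit_between)
  records$stage_salient <- records$stage_specific &
    !is.na(records$adj_p_vs_control) &
    records$adj_p_vs_control < alpha_control &
    rowSums(pb < alpha_between) == 3
  records$stage_salient[is.na(records$stage_salient)] <- FALSE
  message(sprintf("stage-salient genes: %s",
                  paste(sprintf("%s: %d", tumor_stages(),
                                table(factor(records$assigned_stage[records$stage_salient],
                                             tumor_stages()))),
                        collapse = ", ")))
  records
}

#' Per-stage top-k candidate tables
#'
#' For each stage: when at least `k` genes are strictly salient, the top `k`
#' by stage-vs-control adjusted p; otherwise the salient genes first, padded
#' with the stage-specific genes of lowest pval_pdt, up to `k`
#' (fallback-augmented list). For stage III an additional rule applies: every
#' stage-III-specific gene with pval_pdt below `stage3_cutoff` is kept in the
#' returned table (possibly more than `k` rows), with `in_top_k` marking the
#' leading `k`.
#'
#' @param records filtered records from [salience_filter()].
#' @param k list length per stage (default 10).
#' @param stage3_cutoff pval_pdt cutoff for the stage-III rule
#'   (default 1.25e-4).
#' @return named list of per-stage data.frames with columns of `records` plus
#'   `in_top_k`.
#' @export
top_stage_table <- function(records, k = 10, stage3_cutoff = 1.25e-4) {
  out <- lapply(tumor_stages(), function(s) {
    rs <- records[!is.na(records$assigned_stage) &
                    records$assigned_stage == s, , drop = FALSE]
    sal <- rs[rs$stage_salient, , drop = FALSE]
    sal <- sal[order(sal$adj_p_vs_control, sal$gene), , drop = FALSE]
    if (nrow(sal) >= k) {
      top <- sal[seq_len(k), , drop = FALSE]
    } else {
      fill <- rs[!rs$stage_salient, , drop = FALSE]
      fill <- fill[order(fill$pval_pdt, fill$gene), , drop = FALSE]
      need <- min(k - nrow(sal), nrow(fill))
      top <- rbind(sal, fill[seq_len(need), , drop = FALSE])
    }
    top$in_top_k <- TRUE
    if (s == "III") {
      extra <- rs[rs$pval_pdt < stage3_cutoff &
                    !(rs$gene %in% top$gene), , drop = FALSE]
      if (nrow(extra)) {
        extra <- extra[order(extra$pval_pdt, extra$gene), , drop = FALSE]
        extra$in_top_k <- FALSE
        top <- rbind(top, extra)
      }
    }
    rownames(top) <- NULL
    top
  })
  names(out) <- tumor_stages()
  out
}
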