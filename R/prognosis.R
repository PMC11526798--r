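#' Univariate Cox screening of candidate genes
#'
#' One proportional-hazards fit per gene (partial likelihood, Efron tie
#' handling) of overall survival on continuous log2 expression. Genes with a
#' Wald p-value below `alpha` are flagged as candidates for the multivariate
#' model. Genes whose fit fails or does not converge are excluded with a
#' warning.
#'
#' @param expr genes x samples expression matrix (or an
#'   [annotated_expression()]); columns must cover all samples in `surv`.
#' @param surv survival table: `sample_id`, `time`, `event`.
#' @param genes gene symbols to screen.
#' @param alpha candidate cutoff on the Wald p (default 0.05).
#' @return data.frame: `gene`, `beta`, `hr`, `se`, `p`, `candidate`.
#' @export
univariate_cox_screen <- function(expr, surv, genes, alpha = 0.05) {
  values <- if (inherits(expr, "annotated_expression")) expr$values else expr
  m <- match(surv$sample_id, colnames(values))
  if (anyNA(m)) stop("survival table contains samples absent from expression")
  if (sum(surv$event) == 0) stop("no events: survival analysis undefined")
  y <- survival::Surv(surv$time, surv$event)
  rows <- lapply(genes, function(g) {
    x <- values[g, m]
    fit <- tryCatch(
      survival::coxph(y ~ x, ties = "efron"),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || anyNA(stats::coef(fit))) {
      warning("Cox fit failed or did not converge for gene ", g,
              "; excluded", call. = FALSE)
      return(NULL)
    }
    s <- summary(fit)
    data.frame(gene = g, beta = unname(stats::coef(fit)),
               hr = unname(exp(stats::coef(fit))),
               se = unname(sqrt(diag(stats::vcov(fit)))),
               p = unname(s$coefficients[1, "Pr(>|z|)"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no gene could be fit")
  out$candidate <- out$p < alpha
  rownames(out) <- NULL
  out
}

#' Multivariate Cox model with backward AIC selection
#'
#' Starts from the full multivariate proportional-hazards fit over the
#' candidate genes and repeatedly removes the term whose removal most
#' decreases the model AIC, stopping when no removal helps. The resulting
#' risk model carries the gene coefficients of the linear risk score
#' (score = sum of beta_i * expression_i) and a threshold, by default the
#' median training risk score.
#'
#' @param expr genes x samples matrix or [annotated_expression()].
#' @param surv survival table (`sample_id`, `time`, `event`).
#' @param candidates character vector of candidate genes (nonempty).
#' @return object of class `risk_model`: `genes`, `betas`, `threshold`,
#'   `model_p` (likelihood-ratio), `gene_p` (Wald per gene), `concordance`,
#'   `train_scores`, and the underlying `fit`.
#' @export
fit_cox_backward_aic <- function(expr, surv, candidates) {
  if (length(candidates) == 0) stop("empty candidate set")
  values <- if (inherits(expr, "annotated_expression")) expr$values else expr
  m <- match(surv$sample_id, colnames(values))
  if (anyNA(m)) stop("survival table contains samples absent from expression")
  if (sum(surv$event) < length(candidates))
    warning("fewer events (", sum(surv$event), ") than candidate genes (",
            length(candidates), "); selection may be unstable", call. = FALSE)
  dat <- as.data.frame(t(values[candidates, m, drop = FALSE]))
  names(dat) <- candidates
  dat$.time <- surv$time
  dat$.event <- surv$event
  full <- survival::coxph(
    stats::as.formula(paste("survival::Surv(.time, .event) ~",
                            paste(sprintf("`%s`", candidates),
                                  collapse = " + "))),
    data = dat, ties = "efron")
  sel <- stats::step(full, direction = "backward", trace = 0)
  betas <- stats::coef(sel)
  genes <- gsub("`", "", names(betas))
  if (length(genes) == 0) {
    scores <- rep(0, nrow(dat))
    gene_p <- numeric(0)
    model_p <- NA_real_
    conc <- NA_real_
  } else {
    scores <- as.numeric(t(values[genes, m, drop = FALSE]) %*% betas)
    s <- summary(sel)
    gene_p <- stats::setNames(s$coefficients[, "Pr(>|z|)"], genes)
    model_p <- unname(s$logtest["pvalue"])
    conc <- unname(s$concordance["C"])
  }
  structure(
    list(genes = genes, betas = unname(betas),
         threshold = stats::median(scores),
         model_p = model_p, gene_p = gene_p, concordance = conc,
         train_scores = scores, fit = sel),
    class = "risk_model"
  )
}

#' Linear risk score
#'
#' Score = sum over model genes of beta_i * expression_i (log2 units).
#'
#' @param model a `risk_model` (or any list with `genes` and `betas`).
#' @param expressions named numeric vector (one sample) or genes x samples
#'   matrix covering every model gene (hard error on a missing gene).
#' @return numeric score(s), one per sample.
#' @export
compute_risk_score <- function(model, expressions) {
  if (is.null(dim(expressions)))
    expressions <- matrix(expressions, ncol = 1,
                          dimnames = list(names(expressions), "sample_1"))
  missing <- setdiff(model$genes, rownames(expressions))
  if (length(missing))
    stop("missing model gene(s): ", paste(missing, collapse = ", "))
  if (length(model$genes) == 0) return(rep(0, ncol(expressions)))
  drop(crossprod(expressions[model$genes, , drop = FALSE], model$betas))
}

#' Risk stratification and Kaplan-Meier curves
#'
#' Splits samples into high-risk (score strictly above the threshold) and
#' low-risk groups and computes the product-limit survival estimate per group
#' with Greenwood variance and 95% confidence bands.
#'
#' @param scores per-sample risk scores (aligned with `surv` rows).
#' @param surv survival table (`time`, `event`).
#' @param threshold_rule `"median"` (median of `scores`) or `"value"`.
#' @param threshold explicit split point when `threshold_rule = "value"`.
#' @return list: `fit` (a `survfit` object), `groups` (factor low/high),
#'   `threshold`.
#' @export
stratify_and_km <- function(scores, surv,
                            threshold_rule = c("median", "value"),
                            threshold = NULL) {
  threshold_rule <- match.arg(threshold_rule)
  thr <- if (threshold_rule == "median") stats::median(scores)
         else { stopifnot(is.numeric(threshold)); threshold }
  groups <- factor(ifelse(scores > thr, "high", "low"),
                   levels = c("low", "high"))
  if (any(table(groups) == 0))
    stop("risk stratification produced an empty group at threshold ", thr)
  fit <- survival::survfit(
    survival::Surv(surv$time, surv$event) ~ groups,
    conf.type = "log", conf.int = 0.95)
  list(fit = fit, groups = groups, threshold = thr)
}

#' Single-group Kaplan-Meier estimate
#'
#' Product-limit survival estimate with Greenwood variance and 95% bands for
#' one group of samples; the step function is right-continuous.
#'
#' @param surv survival table (`time`, `event`).
#' @return a `survival::survfit` object.
#' @export
km_estimate <- function(surv) {
  if (sum(surv$event) == 0 && nrow(surv) == 0)
    stop("empty survival table")
  survival::survfit(survival::Surv(surv$time, surv$event) ~ 1,
                    conf.type = "log", conf.int = 0.95)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic over the pooled event times with a chi-square
#' reference on 1 degree of freedom.
#'
#' @param surv survival table (`time`, `event`).
#' @param groups two-level factor aligned with `surv` rows.
#' @return list: `chisq`, `p`.
#' @export
logrank_test <- function(surv, groups) {
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) != 2)
    stop("log-rank test needs exactly 2 groups")
  if (sum(surv$event) == 0) stop("no events: log-rank test undefined")
  sd <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ groups)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Harrell's concordance index
#'
#' Fraction of usable (comparable) pairs in which the sample with the higher
#' risk score has the shorter observed survival; tied scores count 0.5.
#'
#' @param scores per-sample risk scores.
#' @param surv survival table (`time`, `event`).
#' @return C-index in \[0, 1\].
#' @export
concordance_index <- function(scores, surv) {
  cc <- survival::concordance(
    survival::Surv(surv$time, surv$event) ~ scores, reverse = TRUE)
  n_pairs <- sum(cc$count[c("concordant", "discordant", "tied.x")])
  if (n_pairs == 0) stop("no comparable pairs")
  unname(cc$concordance)
}

#' Bootstrap uncertainty for the concordance index
#'
#' Resamples patients with replacement and recomputes Harrell's C.
#'
#' @param scores per-sample risk scores.
#' @param surv survival table.
#' @param n_boot number of resamples (default 200).
#' @param seed integer seed.
#' @return list: `c_index`, `se`, `ci` (2.5/97.5 percentiles).
#' @export
concordance_ci <- function(scores, surv, n_boot = 200, seed = 42L) {
  set.seed(seed)
  boots <- replicate(n_boot, {
    i <- sample(length(scores), replace = TRUE)
    tryCatch(concordance_index(scores[i], surv[i, , drop = FALSE]),
             error = function(e) NA_real_)
  })
  list(c_index = concordance_index(scores, surv),
       se = stats::sd(boots, na.rm = TRUE),
       ci = stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE,
                            names = FALSE))
}

#' Per-sample risk report
#'
#' For new samples: the risk score, its quantile within the model's training
#' score distribution, its fold change from the threshold, and the implied
#' risk group.
#'
#' @param model a `risk_model`.
#' @param expressions named vector or genes x samples matrix.
#' @return data.frame: `sample`, `score`, `quantile`, `fold_change`, `group`.
#' @export
risk_report <- function(model, expressions) {
  sc <- compute_risk_score(model, expressions)
  q <- stats::ecdf(model$train_scores)(sc)
  data.frame(sample = if (is.null(names(sc))) seq_along(sc) else names(sc),
             score = unname(sc), quantile = q,
             fold_change = unname(sc) / model$threshold,
             group = ifelse(sc > model$threshold, "high", "low"),
             stringsAsFactors = FALSE, row.names = NULL)
}
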