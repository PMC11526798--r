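#' The 7-gene consensus diagnostic panel
#'
#' The default reduced feature space for the cancer-vs-normal screening
#' model: four top linear-model genes (ESM1, DHRS7C, OTOP3, AADACL2), two
#' stage-salient genes (LPHN3, GABRD) and one linearly monotone gene (LPAR1).
#' Shipped as configuration; any panel may be supplied to the training
#' functions instead.
#'
#' @return character vector of 7 gene symbols.
#' @export
consensus_panel <- function() {
  c("ESM1", "DHRS7C", "OTOP3", "AADACL2", "LPHN3", "GABRD", "LPAR1")
}

#' Assemble the diagnostic feature space
#'
#' De-duplicated union of the stage-salient genes, the top linear-model genes
#' and the linear-and-monotone genes, each tagged with its provenance (first
#' match in that priority order).
#'
#' @param salient_genes,linear_top_genes,linear_monotone_genes character
#'   vectors of gene symbols.
#' @return data.frame: `gene`, `provenance`.
#' @export
assemble_feature_space <- function(salient_genes, linear_top_genes,
                                   linear_monotone_genes) {
  all <- c(salient_genes, linear_top_genes, linear_monotone_genes)
  if (length(all) == 0) stop("empty feature space")
  prov <- rep(c("stage_salient", "linear_top", "linear_and_monotone"),
              c(length(salient_genes), length(linear_top_genes),
                length(linear_monotone_genes)))
  keep <- !duplicated(all)
  out <- data.frame(gene = all[keep], provenance = prov[keep],
                    stringsAsFactors = FALSE)
  message("feature space: ", nrow(out), " genes (",
          length(all) - nrow(out), " duplicates merged)")
  out
}

#' Stratified train/test split
#'
#' Splits samples into train and test sets with the class proportions
#' preserved: per class, `floor(n * test_fraction)` samples (at least 1) go to
#' the test set. Deterministic under `seed`.
#'
#' @param dataset an [annotated_expression()].
#' @param test_fraction fraction held out (default 0.2).
#' @param seed integer seed.
#' @return list with `train` and `test` (both `annotated_expression`).
#' @export
split_stratified <- function(dataset, test_fraction = 0.2, seed = 42L) {
  cls <- dataset$sample_class
  tab <- table(cls)
  if (length(tab) < 2) stop("both classes must be present")
  if (any(tab < 2)) stop("each class needs at least 2 samples")
  set.seed(seed)
  test_idx <- unlist(lapply(levels(cls), function(lv) {
    idx <- which(cls == lv)
    sample(idx, max(1L, floor(length(idx) * test_fraction)))
  }))
  list(train = dataset[, -test_idx], test = dataset[, sort(test_idx)])
}

#' Train the cancer-vs-normal screening classifier
#'
#' Fits one of the supported model kinds on the panel's expression values:
#' `"rf"` — random forest, 500 trees, `mtry = floor(sqrt(p))`;
#' `"svm"` — radial-kernel SVM, cost 0.5, gamma 0.1, with probability
#' estimates; `"nnet"` — single-hidden-layer network, size 1, decay 1.
#' Hyperparameters can be overridden through `params`. Deterministic under
#' `seed`.
#'
#' @param train an [annotated_expression()] (training split).
#' @param panel character vector of feature genes (rows of `train`).
#' @param kind model kind.
#' @param params named list of hyperparameter overrides
#'   (`ntree`, `mtry`, `cost`, `gamma`, `size`, `decay`).
#' @param seed integer seed.
#' @return object of class `screening_model`: list with `model`, `kind`,
#'   `panel`, `seed`, `levels`.
#' @export
train_classifier <- function(train, panel, kind = "rf", params = list(),
                             seed = 42L) {
  kinds <- c("rf", "svm", "nnet")
  if (!kind %in% kinds)
    stop("unknown model kind '", kind, "'; supported: ",
         paste(kinds, collapse = ", "))
  missing <- setdiff(panel, rownames(train$values))
  if (length(missing))
    stop("panel gene(s) absent from data: ", paste(missing, collapse = ", "))
  x <- t(train$values[panel, , drop = FALSE])
  y <- droplevels(train$sample_class)
  set.seed(seed)
  model <- switch(kind,
    rf = randomForest::randomForest(
      x = x, y = y,
      ntree = params$ntree %||% 500,
      mtry = params$mtry %||% max(1, floor(sqrt(length(panel))))),
    svm = e1071::svm(
      x = x, y = y, kernel = "radial",
      cost = params$cost %||% 0.5, gamma = params$gamma %||% 0.1,
      probability = TRUE),
    nnet = nnet::nnet(
      x = x, y = stats::model.matrix(~ y - 1),
      size = params$size %||% 1, decay = params$decay %||% 1,
      maxit = 500, trace = FALSE, softmax = TRUE)
  )
  structure(list(model = model, kind = kind, panel = panel,
                 seed = seed, levels = levels(y)),
            class = "screening_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict class with a confidence probability
#'
#' Returns the predicted class per sample together with the model's
#' probability for that class (ensemble vote fraction for the random forest);
#' in the binary setting the reported probability is at least 0.5 and the two
#' class probabilities sum to 1.
#'
#' @param object a `screening_model`.
#' @param newdata an [annotated_expression()], a samples x genes matrix, or a
#'   named numeric vector for a single sample. All panel genes must be
#'   present (hard error naming the first missing gene).
#' @return data.frame: `sample`, `class`, `probability`.
#' @export
predict_with_confidence <- function(object, newdata) {
  stopifnot(inherits(object, "screening_model"))
  if (inherits(newdata, "annotated_expression"))
    newdata <- t(newdata$values)
  if (is.null(dim(newdata)))
    newdata <- matrix(newdata, 1, dimnames = list("sample_1", names(newdata)))
  missing <- setdiff(object$panel, colnames(newdata))
  if (length(missing))
    stop("missing feature gene: ", missing[1])
  x <- newdata[, object$panel, drop = FALSE]
  prob <- switch(object$kind,
    rf = stats::predict(object$model, x, type = "prob"),
    svm = {
      pr <- stats::predict(object$model, x, probability = TRUE)
      attr(pr, "probabilities")[, object$levels, drop = FALSE]
    },
    nnet = {
      pr <- stats::predict(object$model, x)
      colnames(pr) <- sub("^y", "", colnames(pr))
      pr[, object$levels, drop = FALSE]
    })
  cls <- object$levels[max.col(prob, ties.method = "first")]
  data.frame(sample = rownames(x) %||% seq_len(nrow(x)),
             class = cls,
             probability = prob[cbind(seq_len(nrow(prob)),
                                      max.col(prob, ties.method = "first"))],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Confusion-matrix metric suite
#'
#' All metrics are derived from the four counts and reported as percentages
#' rounded to 2 decimals: sensitivity (recall) = TP/(TP+FN), specificity =
#' TN/(TN+FP), precision = TP/(TP+FP), F1 = 2TP/(2TP+FP+FN), balanced
#' accuracy = (sensitivity+specificity)/2, and the Matthews correlation
#' coefficient MCC = (TP*TN - FP*FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' A metric whose denominator is zero is reported as `NA` (undefined), never
#' as 0.
#'
#' @param TP,FP,FN,TN nonnegative integer counts (total > 0).
#' @return data.frame of class `classifier_metrics`: the counts plus
#'   `sensitivity`, `specificity`, `precision`, `f1`, `balanced_accuracy`,
#'   `mcc`, all on the percent scale.
#' @export
compute_metrics <- function(TP, FP, FN, TN) {
  counts <- c(TP = TP, FP = FP, FN = FN, TN = TN)
  if (any(counts < 0)) stop("confusion counts must be nonnegative")
  if (sum(counts) == 0) stop("empty confusion matrix")
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- frac(TP, TP + FN)
  spec <- frac(TN, TN + FP)
  prec <- frac(TP, TP + FP)
  f1 <- frac(2 * TP, 2 * TP + FP + FN)
  bal <- (sens + spec) / 2
  mcc_den <- prod(sqrt(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  mcc <- if (mcc_den == 0) NA_real_ else (TP * TN - FP * FN) / mcc_den
  out <- data.frame(TP = TP, FP = FP, FN = FN, TN = TN,
                    sensitivity = round(100 * sens, 2),
                    specificity = round(100 * spec, 2),
                    precision = round(100 * prec, 2),
                    f1 = round(100 * f1, 2),
                    balanced_accuracy = round(100 * bal, 2),
                    mcc = round(100 * mcc, 2))
  class(out) <- c("classifier_metrics", class(out))
  out
}

#' Evaluate a screening model on a labelled set
#'
#' Predicts the test samples and summarizes the confusion matrix with
#' [compute_metrics()], treating `"tumor"` as the positive class.
#'
#' @param object a `screening_model`.
#' @param test an [annotated_expression()].
#' @return a `classifier_metrics` row.
#' @export
evaluate_classifier <- function(object, test) {
  pred <- predict_with_confidence(object, test)
  truth <- as.character(test$sample_class)
  compute_metrics(TP = sum(pred$class == "tumor" & truth == "tumor"),
                  FP = sum(pred$class == "tumor" & truth == "control"),
                  FN = sum(pred$class == "control" & truth == "tumor"),
                  TN = sum(pred$class == "control" & truth == "control"))
}
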