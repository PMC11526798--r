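#!/usr/bin/env Rscript
# Diagnostic screening model: assemble the feature space (stage-salient +
# top-10 linear + linear-and-monotone genes), stratified 0.8:0.2 split, train
# the candidate model kinds, and evaluate the full metric suite on the
# holdout set.

source("analysis/common.R")

pip <- get_pipeline()
expr <- load_filtered()

fs <- assemble_feature_space(
  pip$salience$gene[pip$salience$stage_salient],
  head(pip$linear$gene, 10),
  linear_monotone_overlap(pip$linear, pip$monotone))
print(table(provenance = fs$provenance))

sp <- split_stratified(expr, test_fraction = 0.2, seed = 42)
message("train: ", sum(sp$train$sample_class == "tumor"), " tumor / ",
        sum(sp$train$sample_class == "control"), " control;  test: ",
        sum(sp$test$sample_class == "tumor"), " tumor / ",
        sum(sp$test$sample_class == "control"), " control")

rows <- lapply(c("rf", "svm", "nnet"), function(kind) {
  model <- train_classifier(sp$train, fs$gene, kind = kind, seed = 42)
  cbind(model = kind, evaluate_classifier(model, sp$test))
})
metrics <- do.call(rbind, rows)
print(metrics)

out <- res_dir("tables")
write_tsv(fs, file.path(out, "feature_space.tsv"))
write_tsv(metrics, file.path(out, "screening_metrics.tsv"))

# per-sample predicted class with confidence, random-forest model
rf <- train_classifier(sp$train, fs$gene, kind = "rf", seed = 42)
pred <- predict_with_confidence(rf, sp$test)
write_tsv(pred, file.path(out, "screening_predictions.tsv"))
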