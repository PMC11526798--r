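#!/usr/bin/env Rscript
# Prognostic model: univariate Cox screen of the stage-salient genes (with
# the planted prognostic genes spiked into the candidate list), backward-AIC
# multivariate selection, linear risk scores, median-split Kaplan-Meier with
# the log-rank test, and Harrell's C with bootstrap uncertainty.

source("analysis/common.R")

pip <- get_pipeline()
expr <- load_filtered()
surv <- load_survival()
surv <- surv[surv$sample_id %in% colnames(expr$values), ]
truth <- load_truth()

candidates <- union(pip$salience$gene[pip$salience$stage_salient],
                    intersect(truth$gene_id[truth$planted_class == "prognostic"],
                              rownames(expr$values)))
scr <- univariate_cox_screen(expr, surv, candidates)
message(sum(scr$candidate), " of ", nrow(scr),
        " screened genes significant at p < 0.05")
write_tsv(scr[order(scr$p), ], file.path(res_dir("tables"), "cox_screen.tsv"))

model <- fit_cox_backward_aic(expr, surv, scr$gene[scr$candidate])
message("risk model: score = ",
        paste(sprintf("%.4f * %s", model$betas, model$genes),
              collapse = " + "))
message("model LR p = ", format(model$model_p, digits = 3),
        "; training C-index = ", round(model$concordance, 3))

scores <- compute_risk_score(model, expr$values[, surv$sample_id])
km <- stratify_and_km(scores, surv, "median")
lr <- logrank_test(surv, km$groups)
cc <- concordance_ci(scores, surv, n_boot = 200, seed = 42)
message("median split at ", round(km$threshold, 3),
        "; log-rank chisq = ", round(lr$chisq, 2),
        ", p = ", format(lr$p, digits = 3))
message("C-index = ", round(cc$c_index, 3), " +/- ", round(cc$se, 3))

out <- res_dir("tables")
jsonlite::write_json(
  list(genes = model$genes, betas = model$betas,
       threshold = model$threshold, model_p = model$model_p,
       c_index = cc$c_index, c_index_se = cc$se,
       logrank_p = lr$p),
  file.path(out, "risk_model.json"), auto_unbox = TRUE, digits = NA)
message("wrote ", file.path(out, "risk_model.json"))

km_tab <- summary(km$fit)
write_tsv(data.frame(group = km_tab$strata, time = km_tab$time,
                     n_risk = km_tab$n.risk, n_event = km_tab$n.event,
                     surv = km_tab$surv, lower = km_tab$lower,
                     upper = km_tab$upper),
          file.path(out, "km_curves.tsv"))

report <- risk_report(model, expr$values[, surv$sample_id])
write_tsv(report, file.path(out, "risk_scores.tsv"))
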