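test_that("Kaplan-Meier estimate matches the hand product-limit computation", {
  km <- km_estimate(data.frame(time = c(1, 2, 3), event = c(1, 0, 1)))
  s <- summary(km, times = c(1, 3))
  expect_equal(s$surv, c(2 / 3, 0), tolerance = 1e-12)
  # no events: survival stays at 1 throughout
  km0 <- km_estimate(data.frame(time = c(5, 8, 9), event = c(0, 0, 0)))
  expect_true(all(km0$surv == 1))
  # no censoring: KM equals the empirical survival function
  times <- c(2, 4, 4, 7, 10)
  kme <- km_estimate(data.frame(time = times, event = rep(1, 5)))
  emp <- sapply(kme$time, function(t) mean(times > t))
  expect_equal(kme$surv, emp, tolerance = 1e-12)
})

test_that("log-rank statistic matches a brute-force observed-minus-expected oracle", {
  surv <- data.frame(time = c(1, 2, 3, 10, 11, 12), event = rep(1, 6))
  groups <- rep(c("A", "B"), each = 3)
  lr <- logrank_test(surv, groups)
  # oracle: sum over event times of (observed A deaths - expected under
  # hypergeometric), variance-normalized chi-square
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(surv$time))) {
    at_risk <- surv$time >= t
    d <- sum(surv$time == t & surv$event == 1)
    n <- sum(at_risk); nA <- sum(at_risk & groups == "A")
    o_minus_e <- o_minus_e + sum(surv$time == t & surv$event == 1 &
                                   groups == "A") - d * nA / n
    if (n > 1) v <- v + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
  }
  expect_equal(lr$chisq, o_minus_e^2 / v, tolerance = 1e-10)
  expect_equal(lr$p, pchisq(o_minus_e^2 / v, 1, lower.tail = FALSE))
  # invariance under label swap
  lr2 <- logrank_test(surv, rep(c("B", "A"), each = 3))
  expect_equal(lr2$chisq, lr$chisq)
  expect_error(logrank_test(surv, rep("A", 6)), "2 groups")
})

test_that("planted hazard-ratio groups are detected with high power", {
  set.seed(67)
  hits <- 0
  for (r in 1:20) {
    n <- 200
    g <- rep(c("low", "high"), each = n)
    t <- c(rexp(n, 0.01), rexp(n, 0.03))  # hazard ratio 3
    p <- logrank_test(data.frame(time = t, event = 1), g)$p
    hits <- hits + (p < 0.01)
  }
  expect_gte(hits, 18)  # power >= 0.9
})

test_that("concordance index has the stated tie, perfect and null behavior", {
  surv <- data.frame(time = c(1, 2, 3), event = c(1, 1, 1))
  expect_equal(concordance_index(c(5, 5, 5), surv), 0.5)
  expect_equal(concordance_index(c(3, 2, 1), surv), 1)
  set.seed(71)
  n <- 200
  srv <- data.frame(time = rexp(n, 0.01), event = 1)
  cc <- concordance_index(rnorm(n), srv)
  expect_lt(abs(cc - 0.5), 0.05)
  ci <- concordance_ci(rnorm(n), srv, n_boot = 50, seed = 1)
  expect_true(ci$ci[1] < 0.5 & ci$ci[2] > 0.5)
})

test_that("risk score is the stated linear combination", {
  model <- structure(list(genes = c("HOTAIR", "GABRD", "DKK1"),
                          betas = c(0.14872, 0.4423, 0.10877)),
                     class = "risk_model")
  expect_equal(unname(compute_risk_score(model,
                                         c(HOTAIR = 0, GABRD = 0, DKK1 = 0))),
               0)
  expect_equal(unname(compute_risk_score(model,
                                         c(HOTAIR = 1, GABRD = 1, DKK1 = 1))),
               0.69979)
  x <- c(HOTAIR = 2, GABRD = 3, DKK1 = 1)
  model2 <- model; model2$betas <- 2 * model$betas
  expect_equal(compute_risk_score(model2, x), 2 * compute_risk_score(model, x))
  expect_error(compute_risk_score(model, c(HOTAIR = 1, GABRD = 1)), "DKK1")
})

test_that("exchangeable survival data give hazard ratios near 1", {
  set.seed(73)
  vals <- matrix(rnorm(3 * 150, 8), 3, 150,
                 dimnames = list(c("g1", "g2", "g3"), sprintf("s%03d", 1:150)))
  surv <- data.frame(sample_id = colnames(vals),
                     time = rexp(150, 0.01), event = 1)
  scr <- univariate_cox_screen(vals, surv, rownames(vals))
  expect_true(all(abs(log(scr$hr)) < qnorm(0.995) * scr$se))
})

test_that("univariate screen recovers a planted coefficient", {
  cfg <- sim_config(n_per_group = c(20, 100, 100, 100, 100), n_null = 10,
                    n_global_de = 0, n_stage_salient = 0, n_monotone_up = 0,
                    n_monotone_down = 0, n_prognostic = 1, cox_beta = 0.5,
                    censoring_rate = 0, seed = 79)
  ds <- generate_expression_dataset(cfg)
  surv <- generate_survival_outcomes(ds$expr, ds$truth, cfg)
  scr <- univariate_cox_screen(ds$expr, surv, "PROGN0001")
  expect_true(scr$candidate)
  expect_lt(abs(scr$beta - 0.5), 0.15)
  # convergence certificate: the partial-likelihood score is zero at the fit
  m <- match(surv$sample_id, colnames(ds$expr$values))
  fit <- survival::coxph(survival::Surv(surv$time, surv$event) ~
                           ds$expr$values["PROGN0001", m], ties = "efron")
  expect_lt(abs(sum(residuals(fit, type = "score"))), 1e-6)
})

test_that("backward AIC keeps planted genes and drops nulls", {
  recovered <- 0
  for (r in 1:20) {
    cfg <- sim_config(n_per_group = c(10, 100, 100, 100, 100), n_null = 5,
                      n_global_de = 0, n_stage_salient = 0, n_monotone_up = 0,
                      n_monotone_down = 0, n_prognostic = 2, cox_beta = 0.5,
                      censoring_rate = 0, seed = 100 + r)
    ds <- generate_expression_dataset(cfg)
    surv <- generate_survival_outcomes(ds$expr, ds$truth, cfg)
    cands <- c("PROGN0001", "PROGN0002",
               ds$truth$gene_id[ds$truth$planted_class == "null"])
    rm <- fit_cox_backward_aic(ds$expr, surv, cands)
    if (all(c("PROGN0001", "PROGN0002") %in% rm$genes)) recovered <- recovered + 1
    if (r == 1) {
      # candidate order does not change the selected model
      rm2 <- fit_cox_backward_aic(ds$expr, surv, rev(cands))
      expect_setequal(rm2$genes, rm$genes)
      # risk model internals are consistent
      expect_equal(rm$threshold, median(rm$train_scores))
      expect_true(all(rm$gene_p < 1))
      expect_gt(rm$concordance, 0.5)
    }
  }
  expect_gte(recovered, 16)  # selection recovery probability >= 0.8
  expect_error(fit_cox_backward_aic(matrix(1, 1, 1), data.frame(), character(0)),
               "empty candidate")
})

test_that("a lone strong candidate is kept, a lone null candidate dropped", {
  cfg <- sim_config(n_per_group = c(10, 100, 100, 100, 100), n_null = 1,
                    n_global_de = 0, n_stage_salient = 0, n_monotone_up = 0,
                    n_monotone_down = 0, n_prognostic = 1, cox_beta = 0.5,
                    censoring_rate = 0, seed = 83)
  ds <- generate_expression_dataset(cfg)
  surv <- generate_survival_outcomes(ds$expr, ds$truth, cfg)
  keep <- fit_cox_backward_aic(ds$expr, surv, "PROGN0001")
  expect_equal(keep$genes, "PROGN0001")
  drop <- fit_cox_backward_aic(ds$expr, surv, "NULLG0001")
  expect_length(drop$genes, 0)
})

test_that("median stratification balances groups and ties go low-risk", {
  scores <- c(1, 2, 3, 4, 5, 6)
  surv <- data.frame(time = c(9, 8, 7, 3, 2, 1), event = rep(1, 6))
  km <- stratify_and_km(scores, surv, "median")
  expect_equal(as.integer(table(km$groups)), c(3, 3))
  # an explicit threshold equal to a score sends that sample low-risk
  km2 <- stratify_and_km(scores, surv, "value", threshold = 3)
  expect_equal(as.character(km2$groups[3]), "low")
  expect_error(stratify_and_km(scores, surv, "value", threshold = 10),
               "empty group")
  lr <- logrank_test(surv, km$groups)
  expect_true(lr$p < 1 && lr$chisq > 0)
})

test_that("risk report places new samples on the training distribution", {
  model <- structure(list(genes = c("A", "B"), betas = c(1, -1),
                          threshold = 0,
                          train_scores = seq(-2, 2, length.out = 21)),
                     class = "risk_model")
  rep1 <- risk_report(model, c(A = 3, B = 1))   # score 2: top of training
  expect_equal(rep1$score, 2)
  expect_equal(rep1$quantile, 1)
  expect_equal(rep1$group, "high")
})
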