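test_that("contrast matrices are the literal stagewise tables", {
  C1 <- make_contrast_matrix("stage_vs_control")
  expect_equal(rownames(C1), c("control", "I", "II", "III", "IV"))
  expect_equal(unname(C1["control", ]), rep(-1, 4))
  expect_equal(unname(C1["I", ]), c(1, 0, 0, 0))
  expect_equal(unname(diag(C1[-1, ])), rep(1, 4))
  C2 <- make_contrast_matrix("between_stages")
  expect_equal(colnames(C2),
               c("I-II", "I-III", "II-III", "I-IV", "II-IV", "III-IV"))
  expect_equal(unname(C2["control", ]), rep(0, 6))
  expect_equal(unname(C2["I", ]), c(-1, -1, 0, -1, 0, 0))
  expect_equal(unname(C2["II", ]), c(1, 0, -1, 0, -1, 0))
  expect_equal(unname(C2["III", ]), c(0, 1, 1, 0, 0, -1))
  expect_equal(unname(C2["IV", ]), c(0, 0, 0, 1, 1, 1))
  expect_true(all(colSums(C1) == 0) && all(colSums(C2) == 0))
})

test_that("contrast estimates are differences of group means under equal weights", {
  set.seed(23)
  stages <- rep(c("control", "I", "II", "III", "IV"), times = c(8, 4, 6, 5, 3))
  y <- matrix(rnorm(30 * length(stages), 8), 30,
              dimnames = list(sprintf("g%02d", 1:30),
                              sprintf("s%02d", seq_along(stages))))
  fit <- fit_gene_models(y, build_design(stages, "cellmeans"))
  gm <- group_means_oracle(y, stages)
  cf1 <- apply_contrasts(fit, make_contrast_matrix("stage_vs_control"))
  expect_equal(unname(cf1$lfc), unname(gm[, 2:5] - gm[, 1]), tolerance = 1e-10)
  cf2 <- apply_contrasts(fit, make_contrast_matrix("between_stages"))
  expect_equal(unname(cf2$lfc[, "II-IV"]), unname(gm[, "IV"] - gm[, "II"]),
               tolerance = 1e-10)
  # a zero contrast estimates 0 with p = 1
  C0 <- cbind(make_contrast_matrix("stage_vs_control"), zero = 0)
  cf0 <- apply_contrasts(fit, C0)
  expect_equal(unname(cf0$lfc[, "zero"]), rep(0, 30))
  expect_equal(unname(cf0$p[, "zero"]), rep(1, 30))
  expect_error(apply_contrasts(fit, C0[1:3, , drop = FALSE]), "match")
})

test_that("stage assignment takes the argmax |lfc| above a strict threshold", {
  lfc <- rbind(gA = c(2.5, 1.0, 0.5, 0.2),
               gB = c(1.9, 1.9, 1.9, 1.9),
               gC = c(-3.0, 1.0, 2.9, -2.95),
               gD = c(2.1, 2.1, 2.1, 2.1))   # exact tie: earliest stage
  colnames(lfc) <- c("I", "II", "III", "IV")
  cf <- fake_contrast_fit(lfc)
  rec <- suppressMessages(assign_stage_specificity(cf))
  expect_equal(rec$assigned_stage, c("I", NA, "I", "I"))
  expect_equal(rec$stage_specific, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(rec$max_abs_lfc, c(2.5, 1.9, 3.0, 2.1))
})

test_that("the four-pronged filter and pval_pdt follow the stated criteria", {
  lfc <- rbind(gA = c(0.1, 3.0, 0.2, 0.1),   # stage II, all criteria pass
               gB = c(0.1, 3.0, 0.2, 0.1),   # fails criterion (i)
               gC = c(0.1, 3.0, 0.2, 0.1),   # fails one between-stage p
               gD = c(1.0, 1.2, 1.1, 1.3))   # not specific
  colnames(lfc) <- c("I", "II", "III", "IV")
  adj_p <- matrix(1, 4, 4, dimnames = dimnames(lfc))
  adj_p[c("gA", "gC"), "II"] <- 1e-5
  adj_p["gB", "II"] <- 0.01               # > 0.001
  cf_ctrl <- fake_contrast_fit(lfc, p = adj_p / 10, adj_p = adj_p)
  rec <- suppressMessages(assign_stage_specificity(cf_ctrl))
  pB <- matrix(1, 4, 6,
               dimnames = list(rownames(lfc),
                               c("I-II", "I-III", "II-III", "I-IV", "II-IV",
                                 "III-IV")))
  pB[c("gA", "gB"), c("I-II", "II-III", "II-IV")] <- 0.01
  pB["gC", c("I-II", "II-III")] <- 0.01
  pB["gC", "II-IV"] <- 0.2                # one failing between-stage p
  cf_btw <- fake_contrast_fit(pB * 0, p = pB)
  out <- suppressMessages(salience_filter(rec, cf_btw))
  expect_equal(out$stage_salient, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$pval_pdt[1], 0.01^3)
  expect_equal(out$pval_pdt[3], 0.01 * 0.01 * 0.2)
  expect_true(is.na(out$pval_pdt[4]))
  # monotonicity: improving one between-stage p can only lower pval_pdt
  pB2 <- pB
  pB2["gA", "I-II"] <- 0.001
  out2 <- suppressMessages(
    salience_filter(rec, fake_contrast_fit(pB2 * 0, p = pB2)))
  expect_lt(out2$pval_pdt[1], out$pval_pdt[1])
})

test_that("three between-stage p-values at 0.05 give the printed cutoff", {
  lfc <- rbind(g1 = c(3, 0, 0, 0))
  colnames(lfc) <- c("I", "II", "III", "IV")
  rec <- suppressMessages(assign_stage_specificity(fake_contrast_fit(lfc)))
  pB <- matrix(0.05, 1, 6,
               dimnames = list("g1", c("I-II", "I-III", "II-III", "I-IV",
                                       "II-IV", "III-IV")))
  pdt <- compute_pval_pdt(rec, fake_contrast_fit(pB * 0, p = pB))
  expect_identical(pdt, 0.05^3)
  expect_equal(pdt, 1.25e-4)
  # a p of 1 drops out of the product; (1,1,1) gives 1
  pB[1, ] <- 1
  expect_equal(compute_pval_pdt(rec, fake_contrast_fit(pB * 0, p = pB)), 1)
})

test_that("top-stage tables use salient-first fill and the stage-III cutoff rule", {
  mk <- function(stage, n, salient, pdt, adj) {
    data.frame(gene = sprintf("%s%02d", stage, seq_len(n)),
               assigned_stage = stage, stage_specific = TRUE,
               stage_salient = salient, pval_pdt = pdt,
               adj_p_vs_control = adj, stringsAsFactors = FALSE)
  }
  rec <- rbind(
    mk("I", 15, TRUE, 1e-6, seq(1e-9, 1e-5, length.out = 15)),  # k+5 salient
    mk("II", 12, FALSE, seq(1e-5, 1e-3, length.out = 12), 0.5), # 0 salient
    mk("III", 20, FALSE, c(rep(1e-5, 17), rep(0.5, 3)), 0.5),   # 17 below cutoff
    mk("IV", 3, c(TRUE, TRUE, FALSE), c(0.9, 0.8, 1e-4), c(1e-6, 1e-7, 0.4)))
  top <- top_stage_table(rec, k = 10)
  expect_equal(nrow(top$I), 10)
  expect_equal(top$I$gene, sprintf("I%02d", 1:10))     # best adj p first
  expect_equal(nrow(top$II), 10)
  expect_equal(top$II$gene, sprintf("II%02d", 1:10))   # lowest pval_pdt fill
  expect_equal(nrow(top$III), 17)                      # all under cutoff kept
  expect_equal(sum(top$III$in_top_k), 10)
  # sparse stage IV: the two salient genes first (by adj p), then pdt fill
  expect_equal(top$IV$gene[1:3], c("IV02", "IV01", "IV03"))
})

test_that("planted stage-salient genes are recovered and disjoint across stages", {
  cfg <- sim_config(n_per_group = 30, n_null = 150, n_global_de = 10,
                    n_stage_salient = 8, n_monotone_up = 0,
                    n_monotone_down = 0, n_prognostic = 0, seed = 31)
  ds <- generate_expression_dataset(cfg)
  res <- suppressMessages(run_stagewise_pipeline(ds$expr))
  rec <- res$salience
  truth <- ds$truth
  sal <- truth[truth$planted_class == "stage_salient", ]
  found <- rec[rec$stage_salient, ]
  expect_true(all(sal$gene_id %in% found$gene))
  expect_equal(found$assigned_stage[match(sal$gene_id, found$gene)],
               sal$target_stage)
  # equal-lfc global genes are never salient: between-stage contrasts are null
  glob <- truth$gene_id[truth$planted_class == "global_de"]
  expect_false(any(glob %in% found$gene))
  # each gene is assigned to exactly one stage: salient sets are disjoint
  expect_false(anyDuplicated(found$gene) > 0)
})

test_that("stage-vs-control contrasts equal the baseline coefficients", {
  set.seed(41)
  stages <- rep(c("control", "I", "II", "III", "IV"), each = 6)
  y <- matrix(rnorm(25 * 30, 8), 25,
              dimnames = list(sprintf("g%02d", 1:25), sprintf("s%02d", 1:30)))
  bl <- fit_gene_models(y, build_design(stages, "baseline"))
  cm <- fit_gene_models(y, build_design(stages, "cellmeans"))
  cf <- apply_contrasts(cm, make_contrast_matrix("stage_vs_control"))
  expect_equal(unname(cf$lfc),
               unname(bl$coefficients[, c("I", "II", "III", "IV")]),
               tolerance = 1e-8)
})
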