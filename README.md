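# stagewiseDE

Discrete-stage biomarker discovery from stage-annotated bulk expression
data, built for cancer cohorts of the TCGA COADREAD type: tumor samples
carrying an AJCC pathologic stage (I–IV) alongside adjacent-normal controls.
The package asks three questions a staging-aware screening program cares
about — which genes are *salient* to exactly one stage, which genes track
progression *monotonically* from control through stage IV, and whether those
genes carry diagnostic and prognostic signal — and answers them with a
tested, reusable pipeline plus a synthetic-data generator with planted
ground truth, so every stage of the analysis is verifiable without any
download.

## The models

**Stagewise linear model.** For each gene, expression *y* on voom-transformed
log-CPM is fit by weighted least squares against stage indicators:

    y = α + β₁x₁ + β₂x₂ + β₃x₃ + β₄x₄

where α is baseline (control) expression and βᵢ the stage-*i* log
fold change. Residual variances are shrunk by empirical Bayes toward a
shared prior (prior df *d₀*, prior variance *s₀²*), giving moderated t and F
statistics; F p-values over β₁..β₄ are Benjamini–Hochberg adjusted.

**Stage salience.** A cell-means version of the same model (one coefficient
per group, no intercept) feeds two literal contrast matrices: the four
stage-vs-control contrasts and the six between-stage contrasts. A gene is
*stage-specific* when its maximal |lfc| across stages exceeds 2 (assigned to
the argmax stage) and *stage-salient* when additionally (i) the BH-adjusted
stage-vs-control p of the assigned stage is < 0.001 and (ii)–(iv) the three
raw between-stage p-values involving that stage are all < 0.05. When strict
salience is sparse, candidates are ranked by `pval_pdt`, the product of the
three between-stage p-values — at 0.05 each, exactly 1.25 × 10⁻⁴.

**Monotone progression.** A numeric-stage model `y = aX + b` with
X ∈ (0,1,2,3,4) for (control, I..IV) scores the trend; a gene is a
monotonically expressed gene (MEG) when its five group means are *strictly*
ordered, and a significant MEG at adjusted p < 0.05 on the moderated slope.
Genes that are both significant MEGs and stage-salient are the
*progression-significant* drivers.

**Screening and prognosis.** The diagnostic feature space is the union of
stage-salient genes, the linear-model top 10, and genes both linear-top and
monotone; classifiers (random forest, radial SVM, single-layer net) are
trained on a stratified 0.8:0.2 split and scored with the full
confusion-matrix suite (sensitivity, specificity, precision, F1, balanced
accuracy, MCC). Prognosis uses univariate Cox screening (Efron ties) of the
salient genes, backward-AIC multivariate selection, a linear risk score
`Σ βᵢ · geneᵢ`, a median-split Kaplan–Meier comparison with the log-rank
test, and Harrell's concordance index with bootstrap uncertainty.

## Worked example: the analysis workflow

The `analysis/` drivers run the whole study on a simulated cohort whose
group sizes mirror the reference cohort's class imbalance (51 controls,
57/136/113/52 tumors in stages I–IV), writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # cohort: 960 genes x 409 samples
Rscript analysis/02_preprocess.R    # 960 -> 531 genes (sd < 1 filter)
Rscript analysis/03_linear_models.R # 243 of 531 genes at adj p < 1e-5
Rscript analysis/04_salience.R      # 103 stage-salient genes
Rscript analysis/05_monotone.R      # 117 MEGs; 59 progression-significant
Rscript analysis/06_classifier.R    # holdout 71 tumor / 10 control
Rscript analysis/07_prognosis.R     # risk model, KM split, C-index
```

What the printed numbers mean: the simulated cohort plants 40 stage-salient
genes (lfc 3 in one stage), 60 monotone genes (slope ±0.8 per stage index),
50 globally differentially expressed genes and 10 prognostic genes among 800
nulls. The salience stage recovers all 40 planted salient genes (10 per
stage); the extra stage-IV calls are the planted monotone genes, which are
genuinely stage-IV salient by construction (their largest fold change, 3.2,
is at stage IV and every between-stage step is real). The screening random
forest classifies the 81 holdout samples perfectly, and the prognostic stage
recovers the planted hazard genes:

```
risk model: ... + 0.4524 * PROGN0001 + 0.2281 * PROGN0002 + ...
median split at 15.155; log-rank chisq = 83.2, p = 7.4e-20
C-index = 0.71 +/- 0.016
```

The same machinery accepts real firebrowse-style inputs through
`read_expression_matrix()`, `read_clinical_table()`, `merge_and_annotate()`
and `apply_filters()`; `consensus_panel()` ships the 7-gene diagnostic panel
(ESM1, DHRS7C, OTOP3, AADACL2, LPHN3, GABRD, LPAR1) as default
configuration for `train_classifier()`.

## Package layout

- `R/` — the implementation: synthetic cohort generator, firebrowse ingest
  and voom transform, stagewise/cell-means/numeric models with
  empirical-Bayes moderation, contrasts and salience filter, monotone
  detection, classifier and metric suite, Cox/KM/log-rank/concordance.
- `analysis/` — the numbered workflow drivers above.
- `vignettes/stage-salient-biomarkers.Rmd` — the methods notes: model
  assumptions, parameter choices, what the generator does and does not
  emulate, numerical edge cases, limitations.
- `tests/testthat/` — unit, property and end-to-end recovery tests.
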