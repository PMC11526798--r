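---
title: "Stage-salient biomarker discovery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-salient biomarker discovery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records how the pipeline's statistics are defined, which
parameters matter and why their defaults are what they are, what the
synthetic cohort generator does and does not emulate, and the numerical and
design choices made where more than one reasonable option existed. It states
no empirical claim that the test suite and `scripts/acceptance.R` do not
themselves compute.

## The modelling chain

The pipeline operates on a log2-scale gene-by-sample matrix annotated with a
per-sample class (control or tumor) and a collapsed AJCC stage (I–IV).
Because the firebrowse dialect ships RSEM values already log2-transformed
while the mean–variance machinery wants count-like input, the pipeline takes
the antilog (`2^v − 1`, clipped at zero) and runs a voom transform: log-CPM
with the standard 0.5/+1 offsets, and per-observation inverse-variance
weights from a lowess trend (span 0.5) of sqrt residual standard deviation
against average log count. Every downstream model is a weighted
least-squares fit with those weights.

Three designs share one empirical-Bayes engine:

* **baseline** — intercept plus four stage indicators. The intercept is
  control-level expression; each stage coefficient is that stage's log fold
  change versus control. A moderated F over the four stage coefficients
  (excluding the intercept), BH-adjusted across genes, ranks globally
  stage-responsive genes.
* **cell means** — five disjoint group indicators, no intercept, so each
  coefficient is a group mean. This is the design contrasts are applied to:
  the four stage-vs-control columns (+1 on the stage, −1 on control) and the
  six between-stage columns (−1 on the earlier stage, +1 on the later). With
  equal weights the stage-vs-control contrasts equal the baseline
  coefficients exactly; this cross-model identity is enforced by tests at
  1e-8.
* **numeric stage** — intercept plus X ∈ (0,1,2,3,4) for
  (control, I, II, III, IV). The moderated slope p-value scores monotone
  trend strength.

Moderation shrinks per-gene residual variances toward a prior estimated by
the moments method on log variances (trigamma inversion), yielding t and F
statistics on augmented degrees of freedom. Two limiting behaviors are
worth noting: when all genes share one residual variance the posterior
equals that variance (no shrinkage), and when every residual variance is
zero the prior df is infinite and a warning is emitted.

## Salience and its thresholds

A gene is **stage-specific** when max |lfc| over the four stage-vs-control
contrasts strictly exceeds 2 (log2 units); it is assigned to the argmax
stage, the earliest stage winning exact ties (a deterministic rule chosen
because ties must resolve somehow; at float resolution they essentially
never occur on real data). It is **stage-salient** when four criteria hold:
(i) the BH-adjusted stage-vs-control p-value of the assigned stage is below
0.001, and (ii)–(iv) the three raw between-stage p-values involving that
stage are below 0.05. Two deliberate readings are built in and switchable:

* Criteria (ii)–(iv) use *raw* p-values; "adjusted" is reserved for
  criterion (i). `salience_filter(between_adjusted = TRUE)` flips this.
* The BH universe for criterion (i) is every gene surviving the variance
  filter, not only the |lfc| > 2 subset — the adjustment is computed on the
  full contrast fit before thresholding.

`pval_pdt` — the product of the three between-stage p-values for the
assigned stage — is computed for *all* stage-specific genes so that the
fallback ranking is total. At the conventional 0.05 per-contrast level the
product is exactly 1.25e-4, which is also the cutoff the stage-III rule of
`top_stage_table()` applies. The per-stage top-k rule is: k best salient
genes by stage-vs-control adjusted p when a stage has at least k; otherwise
salient genes first and lowest-`pval_pdt` stage-specific genes as fill.

Monotone detection is intentionally crude and strict: five group means on
the voom log-CPM matrix (the same matrix every model sees — consistency,
since nothing in the procedure pins the matrix down otherwise), compared
with strict inequalities and no tolerance. A tie of 1e-12 breaks
monotonicity by design; significance is then left entirely to the moderated
slope p-value, which is tolerant of small non-monotonic wiggles the strict
rule rejects. Progression-significant genes are the intersection of
significant MEGs with stage-salient genes.

## Screening and prognosis

The diagnostic feature space is the union (with provenance) of the
stage-salient genes, the linear top 10, and significant MEGs inside the
linear top 200. The split is stratified per class at `floor(n * fraction)`
test samples. Model kinds are random forest (500 trees,
`mtry = floor(sqrt(p))`; the printed tuning value 2.83 ≈ √8 is accepted via
`params$mtry`), radial SVM (cost 0.5, gamma 0.1) and a single-hidden-layer
network (size 1, decay 1). A two-or-more-hidden-layer perceptron is not
offered: no supported backend implements one, and the model ranking the
workflow reports does not require it. Metrics are computed from the four
confusion counts only, as percentages rounded to two decimals; a metric
with a zero denominator is reported as `NA` — undefined, never zero.
Balanced accuracy is always `(sensitivity + specificity)/2` recomputed from
the counts.

Prognosis screens candidates by univariate Cox fits on continuous log2
expression (Efron tie handling) at p < 0.05, then runs backward selection
from the full multivariate fit, removing whichever term most decreases AIC
until no removal helps. The risk score is the linear combination of the
selected genes' expressions with their Cox coefficients; the default
stratification threshold is the *median training score* (an explicit
threshold is also accepted; maximally-selected-rank thresholding is out of
scope). A sample exactly at the threshold is low-risk — again a
deterministic tie rule. Kaplan–Meier curves use Greenwood variance with 95%
bands; the log-rank statistic is referenced to chi-square on 1 df;
concordance is Harrell's C (score ties count 0.5) with a seeded 200-resample
bootstrap for uncertainty. Dichotomization is for display and testing only —
screening is always on the continuous covariate.

## What the generator emulates, and what it does not

`sim_config()` defaults are the study conditions: group sizes
(51, 57, 136, 113, 52) mirroring the reference cohort's class imbalance;
Gaussian noise with sd 1 on the log2 scale around a baseline of 8 (log2 RSEM
values of moderately expressed genes); planted stage-salient genes at
|lfc| = 3 in exactly one stage (zero elsewhere, so the target stage strictly
dominates); global-DE genes at the same lfc in all four stages (their
between-stage contrasts are null, so they can never be salient — a designed
negative control); monotone genes on an exact line of slope ±0.8 per stage
index; and prognostic genes that are expression-null but act on the hazard,

> hazard = h₀ · exp(Σ β · (x − baseline)),   h₀ = 5e-4 per day, β = 0.5,

centred at the baseline mean so h₀ stays interpretable as an average
patient's hazard (about a 3.8-year median survival) regardless of how many
prognostic genes are planted; Cox estimates are invariant to the centring.
Censoring is administrative at the empirical (1 − rate) quantile of the
simulated event times, the simplest mechanism that is independent of the
covariates; the degenerate `censoring_rate = 1` censors every record.

Deliberately not emulated: batch effects, library-size artifacts,
count-level overdispersion structure (noise is Gaussian on the log scale, so
the voom trend on simulated data is flatter than on real counts),
correlation between genes, and cohort distribution shift. Consequently a
passing recovery test demonstrates that the *inference machinery* finds what
the model class defines, not that real cohorts are this clean; effect sizes
on real data sit closer to the thresholds and the contamination of salient
calls by strong monotone genes (see below) is a real phenomenon, not an
artifact.

One interaction deserves emphasis: a planted monotone gene with slope 0.8
has lfc 3.2 at stage IV and four genuinely distinct group means, so it
*is* stage-IV salient under the definition. Recovery tests therefore
evaluate the salience filter on cohorts without monotone genes and the
monotone detector on cohorts without salient genes; the end-to-end workflow
keeps both and reports the overlap for what it is.

## Numerical choices and degenerate inputs

* Variance filter: strict `sd < 1` over all retained samples (controls
  included), computed on the log2 input before voom; a gene at exactly 1.0
  is retained. Applied after dropping NA-stage tumors; idempotent.
* Duplicate gene symbols keep the highest-variance row; duplicate barcodes
  are not collapsed (each column is a sample); malformed barcodes are
  excluded with a per-sample warning, never silently.
* Sub-stage collapse strips one trailing A/B/C (case-insensitive) after
  removing a leading "stage"; both roman and arabic numerals parse.
* Rank-deficient designs are a hard error naming the collinear columns —
  absent stages produce all-zero indicator columns on purpose so the error
  is informative rather than silent.
* A zero contrast column estimates 0 with p = 1 (the moderated t is 0/0
  there; the convention is harmless and keeps downstream products defined).
* Fewer than 10 genes: the mean–variance trend is not estimable; constant
  unit weights with a warning. A perfectly flat matrix likewise gets
  constant weights (the lowess interpolation is undefined on a single
  point).
* BH adjustment validates [0, 1], propagates NAs without disturbing ranks,
  and is exactly the step-up construction (tested against a brute-force
  implementation).
* Trigamma inversion tolerance is the backend default (well below 1e-8);
  linear-ranking ties break by max |lfc| descending, then gene id.

## Problem sizes

The simulated study cohort is 960 genes by 409 samples — large enough that
the variance filter, the BH universe and the moderation prior behave as they
would at transcriptome scale, small enough that the complete workflow,
test suite and acceptance run finish in well under a minute. Recovery
checks use 50 samples per group for expression effects (SEM ≈ 0.2 on an lfc,
so planted effects of 3 are ~15 SEs from null) and 400 tumor samples for Cox
recovery; null controls use 20 replicate cohorts of 300 null genes.

## Known limitations

* The voom reimplementation is the standard published formulation; on data
  whose mean–variance relation departs from lowess-smoothable form the
  weights are only as good as the trend.
* Backward-AIC selection inherits AIC's liberality with correlated
  candidates; with fewer events than candidates it warns but proceeds.
* The `pval_pdt` product is a ranking heuristic, not a calibrated p-value;
  it is never interpreted as one.
* Classifier probability output for the random forest is the ensemble vote
  fraction — a confidence, not a calibrated posterior.
* External-cohort harmonization (batch correction, platform mapping) is out
  of scope; inputs are assumed RSEM-normalized log2 matrices in the
  firebrowse dialect.
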