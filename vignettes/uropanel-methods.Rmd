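---
title: "Urinary proteome prognostic panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Urinary proteome prognostic panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`uropanel` implements a label-free urinary proteomics workflow for
predicting renal outcomes in type 2 diabetes: correction of raw LFQ
intensities for spot-urine dilution, endogenous reference-protein
normalization, completeness filtering and local least squares imputation,
Mann–Whitney volcano screening, AUC-based random-forest backward
elimination, and random-forest / linear-SVM prognostic panel models whose
0–1 disease scores can be applied, frozen, to external gene-expression
data. This vignette explains the underlying models, the defaults, and the
design decisions a user may want to revisit.

## The measurement model

A spot urine sample dilutes every protein by an arbitrary, sample-specific
factor, so raw LFQ intensities are not comparable across samples. The
pipeline handles this in two steps.

**Correction.** Each sample's raw intensities are divided by its urinary
creatinine and total protein concentrations (`correct_lfq()`, mode
`"both"` by default; creatinine-only and total-protein-only modes are
available). Creatinine is excreted at a roughly constant rate, so its
concentration is a proxy for dilution.

**Endogenous reference normalization.** Correction by chemistry
measurements leaves a residual per-sample technical factor. Six endogenous
reference proteins are selected among the completely quantified candidates
by three criteria applied in order: (1) quantified in every sample,
(2) no group difference (two-sided Mann–Whitney p > 0.05, unadjusted — the
point is to *exclude* outcome-associated proteins, so the raw threshold is
the conservative choice), (3) top-ranked stability. Each reference
protein's corrected value is divided by its cohort median; the per-sample
median of these six ratios is the normalization scaling factor (NSF), and
every other protein is divided by its sample's NSF. By construction the
median reference ratio after scaling is exactly 1 in every sample, which
the test suite asserts at 1e-12 (the even-set median is a mean of two
values, so division is exact only to one ulp). `compute_nsf()` can reuse
frozen reference medians, which is how new samples are scaled against a
fixed discovery cohort; with frozen medians, multiplying one sample by a
constant multiplies its NSF by the same constant and leaves its
normalized profile unchanged.

**Stability.** The stability estimator follows the NormFinder family of
analysis-of-variance decompositions, on log2 corrected values: per-sample
averages over the candidate set are removed (absorbing global level
differences), then for each candidate and group we estimate the deviation
of its group mean from the candidate-set average and its within-group
variance. The deviation is shrunken towards zero by the empirical
between-candidate variance of deviations (an empirical-Bayes step: when
the candidates as a whole show no group structure, individual deviations
are treated as noise). The stability value is the group average of
|shrunken deviation| + sqrt(within-group variance / group size); lower is
more stable. A constant candidate therefore ranks first and a
group-shifted candidate ranks last, which the tests verify against an
independently coded transcription of the same formulas.

## Filtering and imputation

LFQ missingness is abundance-dependent (left-censored): a protein absent
from a sample's spectra yields no intensity. Proteins with ≥ 20% missing
entries in either prognosis group are removed (`completeness_filter()`,
strict per-group rule), and remaining gaps are filled by local least
squares imputation (`lls_impute()`): for each incomplete protein, the
k = 10 completely quantified proteins most correlated with it (absolute
Pearson on log2 values over its observed samples, minimum overlap 6) are
used as regressors, and the fit predicts the missing entries. Observed
values are never altered.

The neighbour regression is ridge-stabilized with the penalty chosen per
protein by generalized cross-validation over a small grid spanning zero
(ordinary least squares) to infinity (the intercept-only model, i.e. the
protein mean). This keeps two properties that a fixed choice cannot
combine: a protein that is an exact linear combination of its neighbours
is recovered exactly (the unpenalized solution wins GCV), while weakly
informative neighbours — the typical case when ten regressors meet ~45
observations — are shrunken or dropped entirely instead of overfitted, so
the imputation is never systematically worse than the protein-mean
fallback it generalizes. Two degrees-of-freedom guards protect heavily
censored proteins, for which GCV itself becomes unreliable: at most half
of a protein's observed samples are used as regressors, and penalty
values leaving fewer than two residual degrees of freedom are excluded
from the grid. Imputation runs after normalization, on the scale the
downstream models use.

## Differential screening and univariate ROC

Group differences are screened per protein by the two-sided Mann–Whitney
U test (exact when the smaller group has ≤ 8 samples and no ties; normal
approximation with continuity and tie correction otherwise) together with
the log2 fold change computed as PPG mean minus GPG mean of log2 values.
The volcano classes use strict thresholds |log2FC| > 0.5 and p < 0.05; no
multiplicity correction enters the classification, but Benjamini–Hochberg
q-values are reported alongside. Univariate discrimination is the rank
AUC (ties weighted 1/2), reported oriented as max(A, 1−A) with a
direction flag.

## Panel selection: AUC-based backward elimination

Feature selection is a two-stage random-forest procedure
(`aucrf_select()`):

1. **Backward elimination.** A forest (`ntree_rank`, default 50,000 as in
   the original design; `mtry_rank = 8`) is fitted on all features and the
   out-of-bag AUC recorded; the least-important 20% of features are
   dropped and the forest refitted, down to two features. The optimal set
   is the smallest one attaining the maximal OOB AUC. Ranking uses
   permutation importance (mean decrease in OOB accuracy); Gini ranking is
   available via `ranking = "gini"`.
2. **Selection stability.** The elimination is repeated on the stage-1
   optimal set inside `cv_repeats` rounds of stratified 3-fold
   cross-validation (default 100 rounds). A feature's *selection
   probability* is the fraction of runs whose optimal subset contains it;
   its *importance* is its permutation importance min–max scaled to [0, 1]
   within each run, averaged over runs. Restricting stage 2 to the
   stage-1 optimal set is what makes the reported ranking table a small,
   interpretable object (eleven rows in the reference table shipped as
   `dkd_panel_ranking()`), and it is also what the cross-validated
   selection probabilities are conditioned on.

The final panel is the features with importance strictly above 0.3
(`filter_by_importance()`). The exact scale of a bounded importance score
is a convention; ours (scaled permutation importance) is exposed in the
ranking table so other conventions can be applied downstream.

## Panel models and scores

`train_panel_model()` centers and scales features (parameters learned on
training data and stored with the model), then fits either a random
forest (1000 trees, `mtry = 5`, `nodesize = 5`) or a linear-kernel SVM
(C = 0.1052) with sigmoid (Platt-type) probability calibration.
Performance is estimated by repeated stratified 3-fold cross-validation
(100 repeats for the forest, 10 for the SVM) with preprocessing re-learned
inside each fold; resubstitution AUC is reported separately, since the two
answer different questions and the forest's resubstitution ROC is
optimistic by construction. Scores are the fraction of trees voting for
the poor-prognosis class (RF) or the calibrated class probability (SVM),
both in [0, 1]. Models serialize to portable JSON (trees as node lists;
the SVM as weight vector, bias and calibration constants) and a restored
model reproduces the native scores.

## External application

A frozen panel model can score external expression matrices
(`apply_panel_model()`). Because the model was trained on urinary protein
abundances and external data are typically kidney transcript levels, the
two scales are bridged by per-gene z-scoring within the external dataset
(the default; the alternative `model_preprocessing` applies the stored
training parameters unchanged). Probes are mapped to panel genes by a
user-supplied table and collapsed by mean (`map_panel_features()`).
Group comparisons against a reference disease group use Mann–Whitney
tests with and without Benjamini–Hochberg adjustment.

## The synthetic cohort generator

`generate_cohort()` draws the study design the analysis assumes: 35
good-prognosis and 19 poor-prognosis samples, 1200 proteins with log2
means uniform on [18, 30] and log2 SDs on [0.4, 1.2] (a realistic LFQ
dynamic range), six reference proteins with intrinsic CV ≤ 5% and no
group shift, and five markers shifted by 1.5 of their own SD (half up in
PPG, half down). Three multiplicative per-sample factors mimic the
spot-urine measurement chain: a dilution factor tracked by urinary
creatinine, a loading factor tracked by total protein, and a residual
technical factor (log2 SD 0.4) that only the NSF normalization can
remove. Missingness is missing-not-at-random: the dropout probability is
a logistic function of log2 abundance with slope `mnar_strength`
(default 1.5), with the threshold calibrated so the average missing
fraction hits `missing_rate` (default 15%). The real data's missingness
mechanism is unknown; this left-censoring form is an assumption, and it
is the reason protein-mean imputation is biased upward for masked
entries. Reference proteins are exempt from masking — they emulate
high-abundance endogenous references that are quantified in every run,
and the selection's completeness criterion requires them to be.

What the generator does *not* emulate: co-regulated protein modules
(proteins are conditionally independent given the sample factors, so
between-protein correlation comes only from those factors), batch
effects, peptide-level variation, and any real biology of the planted
markers. Passing tests therefore demonstrate that the statistical
machinery behaves as designed under its own assumptions, not that the
five reference panel genes are recoverable from any particular real
dataset.

## Problem sizes used by the test suite

The test and acceptance runs scale the expensive defaults down to sizes a
single CPU handles comfortably while leaving the procedures unchanged:
ranking forests of 2000 trees (50,000 default), 20 cross-validation
rounds in stage 2 (100 default), cohorts of 150–400 proteins for
normalization and imputation properties, and a 211-protein cohort
(5 markers + 6 references + 200 noise proteins) for the marker-recovery
experiment, with a 200-sample held-out split of the same simulated
proteome for generalization. Marker recovery runs on the cohort's
complete quantification so that it measures the selection procedure
rather than the interaction of markers with the missingness filter (an
abundance-dependent dropout can remove a planted marker before selection
ever sees it — a real phenomenon, but a different one).

## Clinical labelling

eGFR uses the 2009 CKD-EPI serum-creatinine equation
(141 × min(Scr/κ, 1)^α × max(Scr/κ, 1)^−1.209 × 0.993^age × 1.018 if
female × 1.159 if black, with κ/α sex-specific). CKD stages use the
standard half-open bins (≥90, 60–89, 45–59, 30–44, 15–29, <15). A renal
outcome is an eGFR below 60, an annual decline steeper than 3 (by
default the least-squares slope of eGFR on time, which uses all visits;
an endpoint-difference mode is available since with exactly two visits
the two coincide), or CKD progression — a worse final stage combined
with a ≥25% relative eGFR drop from baseline. ACR classes are <30
(normal), 30–300 (microalbuminuria, boundaries inclusive), >300 mg/g
(macroalbuminuria). Baseline tables are compared with Mann–Whitney /
Fisher tests against a Bonferroni threshold of 0.05 divided by the
number of variables (0.05/17 ≈ 0.0029 for the standard 17-variable
table).

## Known limitations

* The stability estimator is a two-group (or multi-group) decomposition
  on complete candidates; it does not handle missingness internally.
* Cross-modality application of a protein-trained model to transcript
  data has no principled scale bridge; per-dataset z-scoring is a
  pragmatic default and results should be read as rank-level evidence.
* The importance scale of the ranking table is a convention (min–max
  scaled permutation importance averaged over CV runs); absolute
  thresholds like 0.3 are only meaningful relative to that convention.
* With 54 samples, forest OOB AUC has substantial variance; the smallest
  set attaining the maximum OOB AUC is therefore itself a noisy choice,
  which is why stage 2 reports selection probabilities rather than a
  single subset.
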