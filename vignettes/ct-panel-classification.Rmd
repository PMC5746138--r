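---
title: "Diagnostic classification of mixed miRNA/mRNA qPCR panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic classification of mixed miRNA/mRNA qPCR panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctpanel)
```

## The problem

Fine-needle aspiration biopsies of suspect pancreatic masses must be
classified as malignant (pancreatic ductal adenocarcinoma, PDAC) or benign
(typically an inflammatory mass of chronic pancreatitis, CP). Cytology on
such material is limited by sampling, cellularity and fibrosis, so
expression-based molecular classifiers are an attractive complement. The
assay format this package targets is a mixed-chemistry TaqMan array card:
96 reaction chambers holding, in the packaged panel, 79 mRNA markers, 5
mRNA reference genes, 9 miRNA markers, 2 small-RNA reference genes and an
18S-rRNA internal control. Each well reports a cycle-threshold (Ct) value;
wells that never amplify within the 40-cycle protocol report
"Undetermined".

`ctpanel` implements the full analysis path from raw Ct tables to a
deployable classifier: normalization, univariate marker scoring, nested
marker selection inside repeated cross-validation, large-margin
classification, subset searches, final retraining, and exploratory
clustering — together with a synthetic-cohort generator so that every
stage is testable without access to patient data.

## Normalization model

Raw Ct values are normalized separately per chemistry. For a marker $g$ of
chemistry $c$ in sample $s$,

$$\Delta Ct(g, s) = Ct(g, s) - \overline{Ct}_{\mathrm{ref}(c)}(s),$$

where $\overline{Ct}_{\mathrm{ref}(c)}(s)$ is the mean Ct of the reference
assays of chemistry $c$ in that sample (RPLP0, PPIA, RPL37A, RPL30, RPS17
for mRNA; RNU44 and RNU48 for miRNA). The 18S-rRNA internal control enters
neither mean. Because every marker and reference of a sample shares that
sample's offsets (input amount, preamplification efficiency), any constant
per-sample Ct shift cancels exactly — the property the test suite checks.

Sign convention: $\Delta Ct$ is *inversely* related to expression (one
cycle higher means roughly half the template). The convention is kept
throughout; only the clustering step negates the matrix so that "high
value = high expression".

**Censored wells.** The literature rarely states how "Undetermined" wells
are handled. We impute them at the cycle cap (40), i.e. at the lowest
observable expression, *before* normalization. This is deterministic,
keeps the matrix finite, and is conservative: a censored marker well can
only push $\Delta Ct$ up, never create spurious expression.

## Marker scoring: single-threshold classifiers

Each marker is scored by the best single-threshold univariate classifier
on its $\Delta Ct$ values. Candidate thresholds are the midpoints between
consecutive distinct sorted values plus one cut below the minimum and one
above the maximum — these enumerate every dichotomy the marker can induce
— and both orientations (positive above / positive below the cut) are
scanned. Two objectives are provided:

* `tnom_score()` — overall accuracy of the best cut (the classical
  threshold-number-of-misclassifications score, expressed as accuracy);
* `tnom_cw_score()` — the class-wise variant: the mean of sensitivity and
  specificity (balanced accuracy) of the best cut. This is the default
  ranking criterion, appropriate for the unbalanced 41-vs-33 cohort.

The orientation scan guarantees a score of at least 0.5. Ties are broken
toward the smaller threshold, and `positive_above` before
`positive_below`, so scores, thresholds and rankings are bit-reproducible.
`rank_markers()` orders markers by score with ties broken by panel
position. The test suite verifies the scan against a brute-force oracle
that evaluates every labeled threshold classifier explicitly.

## Classification model

`train_svm()` fits a soft-margin linear support-vector machine with the
cost parameter fixed at 1 — no tuning, no kernels, no probability
calibration. Two choices the assay literature leaves open were fixed as
package policy:

* **Per-marker z-standardization**, learned on the training samples and
  stored in the model. Margin classifiers are scale-sensitive and
  $\Delta Ct$ ranges differ widely across markers; storing the
  standardization makes serialized models self-contained and makes
  predictions invariant to positive rescaling of any input column.
* **Boundary convention**: a decision value of exactly 0 is called the
  benign class. A fixed documented convention beats an arbitrary one.

The quadratic program is solved by libsvm (via `e1071`) with a fixed
tolerance (1e-6) and no randomized initialization, so identical inputs
give identical weights. `train_topk()` composes ranking and fitting: rank
all markers on the training data, keep the best $k$, fit the SVM — the
selection is part of the trained artifact.

## Validation strategy

All evaluation uses 10×10-fold cross-validation: per run, a seeded
permutation of the cohort is dealt into 10 folds of approximately equal
size; each fold in turn is held out while the *entire* strategy —
including the marker ranking — is refit on the other nine. Ten runs give
100 train/test splits and, on a 74-sample cohort, 740 held-out calls.
Sensitivity (TP/(TP+FN)), specificity (TN/(TN+FP)) and accuracy are
computed per run from the run's pooled confusion counts, then averaged
over runs. Pooling per run (rather than per fold) avoids undefined metrics
on 7-sample test folds; per-fold aggregation is a documented alternative
we did not take.

Folds are stratified by default: with 33 benign samples, unstratified
10-fold splits can strand a training set with hardly any negatives.
Stratification keeps per-class fold counts within one sample and can be
switched off (`cv_spec(stratified = FALSE)`).

Seeding: one user-facing seed expands deterministically into per-run
permutation seeds; in the exhaustive search each subset's cross-validation
seed derives from the subset's bitmask, so results are independent of
evaluation order and the search parallelizes trivially.

Two search drivers sit on top of the harness:

* `exhaustive_mirna_search()` evaluates all $2^9-1 = 511$ non-empty
  subsets of the 9 miRNA markers with the fixed-subset strategy — the
  miRNA-only screen. For the 88-marker combined panel the analogous
  search ($2^{88}-1 \approx 3.09\times10^{26}$ subsets, `subset_count(88)`)
  is infeasible, which motivates the ranking-based alternative:
* `topk_sweep()` runs the top-$k$ strategy for every $k$ from 1 to 88
  under identical splits and tabulates accuracy per top-list size,
  flagging sizes reaching 90% accuracy. Internally the per-split ranking
  is computed once and shared across all $k$ — arithmetically identical
  to, and about 90× faster than, one `cross_validate()` call per $k$.

## Final model and additional lesion classes

`retrain_final()` refits the top-$k$ strategy on the full two-class
cohort at the sweep's best $k$ — the same code path as inside
cross-validation, deliberately not a special case. `classify_lesions()`
applies the frozen model to samples from other lesion types (ampullary,
acinar cell and biliary tract carcinomas; cystadenomas, IPMNs, solid
pseudopapillary tumors) as a binary forced choice and tallies
malignant/benign calls per diagnosis group.

`cluster_heatmap()` provides the exploratory view: complete-linkage
hierarchical clustering of both samples and markers under the
dissimilarity $1 -$ uncentered Pearson correlation
($\sum x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}$, range of the
dissimilarity $[0, 2]$). Because this similarity is sign-sensitive, the
$\Delta Ct$ matrix is negated first so clustering operates on relative
expression. Agglomeration order at tied heights follows input index
order (the `stats::hclust` convention), making leaf orders deterministic.

## The synthetic-data generator

`simulate_cohort()` generates raw Ct cohorts with the structure the
analysis assumes. Per sample of class $y$ and assay $g$:

$$Ct = \mathrm{baseline}(g) + \mathrm{effect}(g)\cdot f(y) +
\varepsilon,\qquad \varepsilon \sim N(0, \sigma^2),$$

with censoring to "Undetermined" applied after noise for draws beyond the
cycle cap. The defaults define the emulated study conditions:

| parameter | default | rationale |
|---|---|---|
| cohort | 41 PDAC + 33 CP | the two-class study cohort size |
| informative markers | 10 of 88 | a small informative subset among many uninformative markers |
| effect size | 2.0 cycles | a 4-fold expression change, typical of validated qPCR markers |
| effect sign | alternating ± | panels mix up- and downregulated markers |
| per-well noise SD | 0.75 cycles | technical + biological spread of FNAB qPCR replicates |
| baseline Ct | uniform in [22, 34] | mid-to-late dynamic range of preamplified targets |
| reference Ct | evenly spaced in [15, 26], SD 0.25 | abundant, stable housekeeping transcripts |
| internal control Ct | 12 | 18S rRNA is far more abundant than any mRNA |
| cycle cap | 40 | the array protocol's cycle count |

Additional lesion classes take the malignant signature on a configurable
fraction of the informative markers: 1.0 for carcinoma-like classes and
0.5 for cyst-like classes (`default_shift_fractions()`), which reproduces
qualitatively the observed behavior — solid carcinomas classified as
malignant, cystic lesions split between the classes. The packaged
39-sample lesion cohort (`lesion_class_counts()`) uses 3 ampullary, 3
acinar cell and 5 biliary tract carcinomas and fills the remainder with
10 cystadenomas, 15 IPMNs and 3 SPTs; only the carcinoma counts are
anchored in published tallies, the cyst-class split is an assumption.

**What the generator does *not* model** — and hence what passing tests do
not show about real data: amplification-efficiency differences between
assays, batch and site effects, contamination, label noise in the gold
standard, correlated marker modules (each marker is conditionally
independent given class), and the real per-class Ct distributions, which
are unknown. Synthetic performance numbers characterize the pipeline's
correctness and power under the stated model, not clinical accuracy.

## Numerical and design choices

* Thresholds only at midpoints of distinct values: the score depends only
  on induced dichotomies, and midpoints enumerate all of them.
* Marker ranking recomputed inside every training fold; selecting on the
  full dataset would leak test information and inflate accuracy (the
  no-leakage property is tested by corrupting held-out labels and
  asserting bit-identical models).
* A constant (zero-variance) marker in a training fold is centered but
  given scale 1 rather than producing a division by zero; its weight is
  then determined by the margin optimization like any other.
* Multi-target assays ("ELA3A,ELA3B", "MUC3A,MUC3B") are single assay
  identifiers — one reaction chamber each; the legacy symbol CDC2 is kept
  as printed on the card. Table delimiters are auto-detected between tab
  and comma, which is why the tab dialect is the default for anything
  containing assay names.
* Undefined metrics (empty class in a confusion table) are flagged `NA`,
  never silently propagated as `NaN`.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise the pipeline at the
study's own scale: 74-sample cohorts on the full 96-assay panel, complete
10×10 cross-validations (100 splits, 740 held-out calls), the full
511-subset miRNA screen and the full 88-size top-list sweep; oracle
comparisons for the threshold scores run on 500 random small instances,
and parameter-recovery / null checks average 10–20 simulated cohorts.
Where a check only needs enumeration bookkeeping rather than statistical
precision, the inner cross-validation is run with fewer repetitions.

## Known limitations

* The 10×10 design estimates generalization for *this* cohort size; it is
  not an external validation.
* With strongly informative synthetic markers the sweep's best top-list
  size is small; the plateau structure of real panels (where dozens of
  weakly informative markers help) appears only when the generator is
  configured with many weak effects.
* No multiple-testing control is applied over the 511 searched subsets;
  the best subset's accuracy is an optimistic order statistic by
  construction, which the null-cohort check makes visible.
* The miRNA-only ceiling and the combined-panel advantage reported for
  the real cohort cannot be reproduced from synthetic data; they depend
  on the real expression distributions.
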