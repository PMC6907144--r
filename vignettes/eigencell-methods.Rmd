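---
title: "Classifying single cells by informative principal-component projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying single cells by informative principal-component projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eigencell)
```

## The model

`eigencell` treats cell-type assignment as supervised classification in
a low-dimensional eigenspace rather than in gene space.  The premise is
that cell identity is encoded in many small, correlated differences in
mean and variance of gene expression, which individual gene tests
dilute: orthogonal components of the expression covariance collect those
small effects into a few axes that a classifier can use.

Given a training count matrix (cells × genes) with known labels:

* counts are normalised to log2(CPM + 1), centred and scaled gene-wise
  (sample standard deviation, n − 1) into a matrix $M$;
* $M = U \Sigma V^{T}$ by truncated SVD; scores $S = U\Sigma$, and the
  variance explained by component $i$ is $s_i^2 / \lVert M \rVert_F^2$
  — the denominator is the exact total sum of squares, not the
  truncated one, so the fractions do not depend on how many components
  were requested;
* components explaining at least 0.01% of the variance form the
  candidate pool $R$; for each class, a two-tailed Wilcoxon rank-sum
  test compares that class's scores on each pooled component against
  all remaining cells, and Benjamini–Hochberg adjusted $p < 0.05$
  defines the class's informative components $F$;
* per class, a soft-margin SVM with Gaussian kernel
  $k(x, x_i) = \exp(-\sigma \lVert x - x_i \rVert^2)$ is trained
  one-versus-all on $F$, and its decision values are mapped to
  probabilities through a Platt sigmoid
  $\Pr(y = 1 \mid f) = 1 / (1 + e^{A f + B})$.

At prediction time, test cells are normalised and standardised with the
*training* $\mu, \sigma$, projected as $P = M_{\text{test}} V$, and
scored by every class model on its own informative components.  The
maximum class probability must strictly exceed a threshold (0.9 by
default) for the cell to be assigned; otherwise it is `Unassigned`.
The one-versus-all probabilities are intentionally not normalised to
sum to one across classes: rejection semantics depend on each model's
absolute calibrated confidence, and renormalising would force an
assignment even when every model is unsure — exactly the failure mode
the rejection option exists to avoid.

Assumptions worth keeping in mind: the training and test data must
share gene identifiers and be on comparable expression scales (the
package standardises with training parameters but performs no batch or
platform alignment); class structure must be linearly visible somewhere
in the eigenspace after the kernel map; and the calibrated probabilities
are only as good as the class composition of the training cohort.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| `n_mads` | 3 | robust QC cut-off on library size and mitochondrial / ribosomal fractions (dimensionless MAD units, 1.4826-scaled) |
| `min_cell_frac` | 0.01 | minimum detection fraction for a gene |
| `min_mean_cpm` | 5 | genes at or below this mean CPM are dropped |
| `n_components` | min(n − 1, genes, 100) | SVD truncation; 100 comfortably covers the ≲ 20 informative components seen in practice while bounding cost |
| `var_threshold` | 1e-4 | variance-explained floor (0.01%) |
| `alpha` | 0.05 | BH-adjusted significance for component selection |
| `folds` | 10 | stratified CV folds for (σ, C) tuning |
| `grid` | quantile heuristic × powers of two | σ from the 0.1/0.5/0.9 quantiles of reciprocal pairwise squared distances; C ∈ {0.25, …, 16} |
| `threshold` | 0.9 | rejection threshold on the maximum class probability (strict `>`) |
| `balance` | `"none"` | optional SMOTE balancing of each one-versus-all training set |
| `min_class_size` | 20 | warning floor; classes under 2 cells are an error |

The threshold is applied at prediction time, so one trained bundle can
be reused at different stringencies; the value stored in the bundle is
only the default.  Model selection maximises mean validation AUROC
because it is threshold-free and matches the reported metrics; ties are
broken toward smaller cost, then smaller σ, preferring the smoother
model.

## What the simulator emulates — and what it does not

`simulate_cells()` draws per-gene baseline means log-normally, shifts a
dedicated, disjoint block of `n_effect_genes` (default 200 of 1000)
upward by `effect_size` log2 units (default 1) per class, and samples
negative-binomial counts (dispersion 0.5) at per-cell library sizes
uniform on 5000–20000, with `MT-`/`RPL`-prefixed genes for the QC
fractions.  Defaults were chosen once as a plausible droplet-scale
regime: many modest effects spread across genes, realistic library-size
spread, moderate overdispersion.  An optional `unseen` class with its
own disjoint effect block supports rejection experiments, and
`simulate_hierarchy()` layers nested effect blocks so sibling leaves
share ancestral shifts.  The generator returns a ground-truth manifest
(effect genes, per-class means, library sizes) so every recovery test
can be audited.

Deliberately absent: gene–gene correlation beyond the shared class
shifts, zero inflation beyond what the NB produces, UMI saturation, and
batch effects (an optional log-mean `batch_shift` exists but no
correction is implemented — degradation under batch shift is a
measurement, not a feature).  Consequently, passing recovery tests show
the pipeline recovers the *kind* of structure it assumes; they say
nothing about platform effects, doublets or ambient RNA in real data.

## Numerical choices

* **SVD sign convention.** Each rotation column is flipped so its
  largest-magnitude loading is positive; otherwise solver-dependent
  sign flips break bundle reproducibility.
* **Zero-variance genes** cannot be standardised and are excluded from
  the scaling (and recorded); test genes missing from the scaling enter
  at the training mean (scaled 0), which is the unbiased placeholder
  that preserves the rotation's dimensions.  Gene overlap below 50%
  between test data and scaling is an error rather than a silent
  near-empty projection.
* **Rank-sum p values** use the exact U distribution when both groups
  have ≤ 8 observations without ties, and the tie-corrected normal
  approximation with continuity correction otherwise.  The test is
  rank-sum, not signed-rank: the one-versus-all groups are unpaired, so
  a paired statistic is not defined.  BH correction is applied within
  one class's family of tests — the variance-filtered pool, since those
  are exactly the hypotheses examined per model.
* **Selection ranking** orders components by adjusted p, breaking ties
  toward the lower component index for determinism.  A class whose
  every adjusted p exceeds α falls back to its single best component
  with a warning, so one degenerate class does not abort a multiclass
  fit.
* **Platt calibration** uses the damped Newton iteration with
  regularised targets $(n_+ + 1)/(n_+ + 2)$ and $1/(n_- + 2)$, run to a
  gradient norm of 1e-8 (cap 100 iterations), on out-of-fold decision
  values — fitting the sigmoid on training-set decisions would inherit
  the SVM's training optimism.  The implementation was checked against
  an independent quasi-Newton optimiser on the same likelihood.
* **Strict threshold.** A cell at exactly the threshold is rejected;
  ties at the maximum probability break lexicographically by class
  name.  `Unassigned` is the single canonical spelling.
* **Bundles** store every array as TSV/JSON text with SHA-256
  checksums.  Probabilities survive the text round-trip to well under
  1e-10; labels are unchanged.
* **Degenerate inputs** fail loudly: empty matrices, all cells removed
  by QC, all genes filtered, zero-total cells, single-class labels, a
  variance filter that keeps nothing.

## Design decisions on genuinely open points

* With exactly two classes, either two independent models or a single
  model with complement probability (`collapse_binary = TRUE`) can be
  used; in the single-model case "both classes above threshold"
  coincides with the max rule by construction, while with two models
  the max rule is applied as stated.
* "Bootstrap" evaluation means repeated stratified 75/25 splits (the
  procedure the reported confidence intervals describe), not
  resampling with replacement; the same seed reproduces the same
  partitions so competing methods can be compared on identical splits.
* AUPRC uses the standard stepwise threshold-sweep convention, under
  which a constant predictor scores the class prevalence rather than
  zero.
* Rejection-aware sensitivity is (true positives assigned the positive
  class) / (all true positives), with unassigned positives in the
  denominator; specificity is the mirror image for negatives.
* The differential-expression baseline screens genes with the package's
  own rank-sum test plus a |log2 FC| > 1 filter rather than an external
  count-model package, keeping the artifact self-contained; it is a
  baseline, not a recommended DE method.

## Problem sizes used by the test suite

The shipped tests run the full pipeline at 200 + 200 training cells ×
1000 genes (the simulator defaults) for recovery and rejection checks,
30 × 60 matrices for decomposition oracles, 1000 replicates for
rank-sum type-I calibration and 200 label permutations for FDR control
— sizes chosen so the whole suite completes in well under a minute of
CPU while leaving each statistical check adequately powered.

## Known limitations

No batch/platform alignment (pre-aligned embeddings must be produced
upstream); no doublet or ambient-RNA handling; probabilities are
per-class calibrated but not jointly coherent across classes; the
hierarchical classifier propagates hard assignments only (a cell
rejected mid-tree keeps its partial path, and errors at the root cannot
be recovered deeper down); and training classes with very few cells
(≲ 200 in practice, warned below 20) degrade sensitivity before
specificity.
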