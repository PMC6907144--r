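# eigencell

Supervised cell-type classification for single-cell RNA-seq by
projection onto an informative principal-component eigenspace.

## The problem

Annotating cells in a new scRNA-seq experiment by eye — clustering, then
hunting marker genes per cluster — is slow, subjective and ignores the
many genes whose individual differences between cell types are too small
to reach significance but which jointly carry most of the discriminative
signal.  `eigencell` is for analysts who already have a well-annotated
reference cohort and want to transfer those labels to independent cells,
including the case where the new data contain cell types the reference
never saw: such cells should be flagged, not forced into a known class.

## The method

Training, on a reference cells × genes count matrix with known labels:

1. **QC and normalisation.** Cells beyond 3 median absolute deviations
   (MADs) from the median library size, mitochondrial fraction or
   ribosomal fraction are removed; genes detected in < 1% of cells or
   with mean CPM ≤ 5 are dropped; counts become log2(CPM + 1).
2. **Eigendecomposition.** The matrix is gene-wise centred and scaled
   (μ, σ with the n − 1 denominator) into *M*, then factorised by
   truncated SVD, *M = UΣVᵀ*.  The scores *S = UΣ* are the principal
   components; component *i* explains *s<sub>i</sub>² / ‖M‖²<sub>F</sub>*
   of the variance, and components explaining < 0.01% are discarded.
3. **Feature selection.** For each class (one-versus-all), every
   retained PC is tested with a two-tailed Wilcoxon rank-sum test of the
   class's scores against the rest; Benjamini–Hochberg adjusted p < 0.05
   selects the class-informative PCs.
4. **Classification model.** A radial-kernel SVM,
   *k(x, xᵢ) = exp(−σ‖x − xᵢ‖²)*, is trained per class on its
   informative PCs.  Cost *C* and kernel width σ are chosen by
   stratified 10-fold cross-validation (highest mean validation AUROC),
   and probabilities come from a Platt sigmoid
   *Pr(y = 1 | f) = 1/(1 + e^{Af + B})* fitted on out-of-fold decision
   values.  Optional SMOTE balancing handles class imbalance.

Prediction, on an independent count matrix: cells are normalised, scaled
with the *training* μ and σ, projected through the stored rotation
(*P = M*<sub>test</sub>*V*), and scored by every class model.  A cell is
assigned the class with the highest probability only if that probability
exceeds a threshold (0.9 by default); otherwise it is labelled
`Unassigned`.  Classifiers can also be arranged in a lineage tree
(e.g. lymphoid → T cell → cytotoxic), each child scoring only the cells
its parent assigned to that branch.

Reported sensitivity and specificity count `Unassigned` cells as
incorrect, so the rejection option is never free.

## Worked example

Everything below is computed by the package's own simulator, so it runs
with no downloads:

```r
library(eigencell)

sim <- simulate_cells(n_cells_per_class = 150, n_genes = 800,
                      n_effect_genes = 150, effect_size = 1, seed = 7)
set.seed(7)
tr <- sort(unlist(lapply(c("classA", "classB"), function(cl)
  sample(which(sim$labels == cl), 110))))
fit <- eigencell(cm_subset(sim$counts, cells = tr), sim$labels[tr],
                 seed = 7)
summary(fit)
#> eigencell model summary
#>   class n_cells informative_pcs support_vectors cv_auroc
#>  classA     106               1              26        1
#>  classB     107               1              26        1
#> rejection threshold 0.9; 100 components retaining 73.2% variance

te <- setdiff(seq_along(sim$labels), tr)
pred <- predict(fit, cm_subset(sim$counts, cells = te))
head(pred, 3)
#>    cell_id    classA     classB max_probability predicted_label
#> 1 cell0001 0.9472266 0.05252353       0.9472266          classA
#> 2 cell0002 0.9864336 0.01348457       0.9864336          classA
#> 3 cell0004 0.9840664 0.01583976       0.9840664          classA

confusion_with_rejection(pred, sim$labels[te], "classA")
#> <metrics_report> positive class 'classA'
#>   sensitivity 1.0000  specificity 1.0000  precision 1.0000  F1 1.0000
```

The summary says each class needed a single informative PC (the
simulated effect is one shared axis); `cv_auroc` is the cross-validated
model-selection score.  Each prediction row carries the unnormalised
one-versus-all probabilities, their maximum, and the assigned label —
`Unassigned` whenever the maximum does not exceed the threshold.
(`cm_subset` is the internal subsetter, `eigencell:::cm_subset`, used
here for brevity.)

Models persist as portable plain-text bundle directories
(`save_model_bundle()` / `load_model_bundle()`, SHA-256-checksummed), and
a thin command-line wrapper (`inst/scripts/eigencell`, subcommands
`train`, `predict`, `evaluate`, `simulate`, `hierarchy-predict`) drives
the same functions from a shell.

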