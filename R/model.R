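#' Fit a projection-based cell-type classifier
#'
#' The full training pipeline: optional 3-MAD quality control, gene
#' filtering, log2(CPM + 1) normalisation, per-gene centring and
#' scaling, truncated SVD, the 0.01% variance-explained filter,
#' per-class informative-PC selection by two-tailed rank-sum tests with
#' Benjamini-Hochberg correction, and one calibrated one-versus-all
#' radial-kernel SVM per class (cost and kernel width tuned by
#' stratified cross-validation on mean validation AUROC, probabilities
#' by Platt scaling on out-of-fold decision values).
#'
#' @param counts a raw-count [cell_matrix()] (cells x genes).
#' @param labels per-cell class labels, aligned with `counts` rows (or
#'   named by cell id).
#' @param qc apply [qc_filter_cells()] first (default `TRUE`).
#' @param mito_pattern,ribo_pattern,n_mads QC parameters.
#' @param gene_filter apply [filter_genes()] (default `TRUE`).
#' @param min_cell_frac,min_mean_cpm gene-filter parameters.
#' @param n_components number of SVD components (default
#'   `min(n_cells - 1, n_genes, 100)`).
#' @param var_threshold variance-explained filter (default 1e-4, i.e.
#'   0.01%).
#' @param alpha BH-adjusted significance level for PC selection.
#' @param folds,grid SVM tuning parameters (10-fold CV by default).
#' @param threshold default rejection threshold stored on the model
#'   (cells whose maximum class probability is not greater than it are
#'   labelled `"Unassigned"`).
#' @param balance `"none"` or `"smote"` (per-class SMOTE balancing of
#'   the one-versus-all training sets).
#' @param min_class_size classes below this size trigger a warning;
#'   classes below 2 cells are an error.
#' @param collapse_binary with exactly two classes, train a single model
#'   for the second (alphabetically) class and report the first class as
#'   its complement probability.
#' @param seed RNG seed for fold assignment, the grid heuristic and
#'   SMOTE.
#' @return An object of class `eigencell` bundling the eigenspace,
#'   per-class PC selections and SVM models, `class_names` and the
#'   rejection `threshold`; methods: `print`, `summary`, `predict`,
#'   `plot`, `coef`.
#' @seealso [predict.eigencell()], [save_model_bundle()]
#' @examples
#' sim <- simulate_cells(n_cells_per_class = 60, n_genes = 300,
#'                       n_effect_genes = 60, effect_size = 1.5, seed = 1)
#' fit <- eigencell(sim$counts, sim$labels, folds = 3, seed = 1)
#' pred <- predict(fit, sim$counts)
#' table(pred$predicted_label, sim$labels)
#' @export
eigencell <- function(counts, labels, qc = TRUE, mito_pattern = "^MT-",
                      ribo_pattern = "^RP[LS]", n_mads = 3,
                      gene_filter = TRUE, min_cell_frac = 0.01,
                      min_mean_cpm = 5, n_components = NULL,
                      var_threshold = 1e-4, alpha = 0.05, folds = 10,
                      grid = NULL, threshold = 0.9,
                      balance = c("none", "smote"), min_class_size = 20,
                      collapse_binary = FALSE, seed = 1) {
  stopifnot(is(counts, "cell_matrix"))
  balance <- match.arg(balance)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  labels <- as.character(labels)
  if (length(labels) != length(counts$cell_ids))
    stop("labels length must match the number of cells")
  names(labels) <- counts$cell_ids
  cl <- match.call()

  if (qc) {
    counts <- qc_filter_cells(counts, mito_pattern, ribo_pattern, n_mads)
    labels <- labels[counts$cell_ids]
  }
  class_names <- sort(unique(labels))
  if (length(class_names) < 2) stop("at least two classes are required")
  sizes <- table(labels)
  if (any(sizes < 2))
    stop("classes with fewer than 2 cells: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  if (any(sizes < min_class_size))
    warning("classes below ", min_class_size, " cells: ",
            paste(names(sizes)[sizes < min_class_size], collapse = ", "))

  if (gene_filter) counts <- filter_genes(counts, min_cell_frac, min_mean_cpm)
  logm <- normalize_log_cpm(counts)
  scaling <- fit_center_scale(logm)
  scaled <- apply_center_scale(logm, scaling)
  space <- fit_eigenspace(scaled, n_components)
  rfil <- filter_by_variance(space, var_threshold)

  model_classes <- if (collapse_binary && length(class_names) == 2)
    class_names[2] else class_names
  selections <- list()
  models <- list()
  for (cn in model_classes) {
    sel <- select_informative_pcs(rfil, labels, cn, alpha)
    if (length(sel$pc_indices) == 0) {
      warning("no PC passed alpha = ", alpha, " for class '", cn,
              "'; falling back to the smallest-adjusted-p PC")
      sel$pc_indices <- as.integer(names(which.min(sel$p_adj)))
    }
    selections[[cn]] <- sel
    pcs <- sort(sel$pc_indices)
    feats <- space$scores[, pcs, drop = FALSE]
    y <- labels == cn
    if (balance == "smote" && sum(y) != sum(!y)) {
      bal <- smote_oversample(feats, y, seed = seed)
      feats <- bal$features
      y <- bal$labels
    }
    models[[cn]] <- tune_and_train_svm(feats, y, folds = folds, grid = grid,
                                       seed = seed, class_name = cn)
    models[[cn]]$pc_indices <- pcs
  }

  structure(list(eigenspace = space, selections = selections,
                 models = models, class_names = class_names,
                 threshold = threshold, labels = labels,
                 collapse_binary = collapse_binary && length(class_names) == 2,
                 parameters = list(alpha = alpha,
                                   var_threshold = var_threshold,
                                   folds = folds, seed = seed,
                                   balance = balance,
                                   n_components = length(space$singular_values)),
                 call = cl),
            class = "eigencell")
}

#' Per-class conditional probabilities for new cells
#'
#' Normalises the raw counts to log2(CPM + 1), centres and scales with
#' the training parameters (genes matched by identifier; training genes
#' absent from the test data enter at the training mean), projects the
#' cells through the stored rotation and evaluates each class's
#' calibrated SVM on its own informative PCs.  One-versus-all
#' probabilities are deliberately not normalised across classes.
#'
#' @param bundle a fitted [eigencell()] model.
#' @param test_counts a raw-count [cell_matrix()].
#' @return A cells x classes matrix of probabilities in \[0, 1\], with
#'   cell ids as row names.
#' @export
predict_probabilities <- function(bundle, test_counts) {
  stopifnot(is(bundle, "eigencell"), is(test_counts, "cell_matrix"))
  if (length(test_counts$cell_ids) == 0)
    return(matrix(numeric(0), 0, length(bundle$class_names),
                  dimnames = list(NULL, bundle$class_names)))
  logm <- normalize_log_cpm(test_counts)
  scaled <- apply_center_scale(logm, bundle$eigenspace$scaling)
  probs <- matrix(NA_real_, nrow(scaled$values), length(bundle$class_names),
                  dimnames = list(test_counts$cell_ids, bundle$class_names))
  for (cn in names(bundle$models)) {
    m <- bundle$models[[cn]]
    p <- project_cells(scaled, bundle$eigenspace, m$pc_indices)
    probs[, cn] <- platt_probability(m, svm_decision(m, p$values))
  }
  if (bundle$collapse_binary) {
    other <- setdiff(bundle$class_names, names(bundle$models))
    probs[, other] <- 1 - probs[, names(bundle$models)]
  }
  probs
}

#' Label assignment with a rejection option
#'
#' A cell is assigned the class with the highest probability when that
#' probability strictly exceeds `threshold`; otherwise it is labelled
#' `"Unassigned"`.  Ties at the maximum are broken by lexicographic
#' class-name order.
#'
#' @param probs cells x classes probability matrix (named columns), as
#'   returned by [predict_probabilities()].
#' @param threshold rejection threshold in (0, 1] (default 0.9).
#' @return Data frame with `cell_id`, one probability column per class,
#'   `max_probability` and `predicted_label`.
#' @export
assign_labels <- function(probs, threshold = 0.9) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  probs <- as.matrix(probs)
  cls <- colnames(probs)
  if (is.null(cls)) stop("probs must have class names as column names")
  ord <- order(cls)                     # lexicographic tie-break
  lab <- character(nrow(probs))
  mx <- numeric(nrow(probs))
  for (i in seq_len(nrow(probs))) {
    p <- probs[i, ord]
    j <- which.max(p)                   # first max in lexicographic order
    mx[i] <- p[j]
    lab[i] <- if (p[j] > threshold) cls[ord][j] else "Unassigned"
  }
  out <- data.frame(cell_id = rownames(probs) %||%
                      as.character(seq_len(nrow(probs))),
                    probs, max_probability = mx, predicted_label = lab,
                    row.names = NULL, check.names = FALSE)
  out
}

#' Classify new cells
#'
#' @param object a fitted [eigencell()] model.
#' @param newdata a raw-count [cell_matrix()].
#' @param threshold rejection threshold; defaults to the one stored in
#'   the model.
#' @param ... unused.
#' @return Data frame with `cell_id`, per-class probabilities,
#'   `max_probability` and `predicted_label` (a class or
#'   `"Unassigned"`).
#' @export
predict.eigencell <- function(object, newdata,
                              threshold = object$threshold, ...) {
  probs <- predict_probabilities(object, newdata)
  assign_labels(probs, threshold)
}

#' @export
print.eigencell <- function(x, ...) {
  cat("<eigencell> one-versus-all RBF-SVM classifier\n")
  cat(sprintf("  classes: %s\n", paste(x$class_names, collapse = ", ")))
  cat(sprintf("  eigenspace: %d cells x %d genes, %d components\n",
              x$eigenspace$n_cells, length(x$eigenspace$gene_ids),
              length(x$eigenspace$singular_values)))
  cat(sprintf("  rejection threshold: %g\n", x$threshold))
  invisible(x)
}

#' @export
summary.eigencell <- function(object, ...) {
  sel <- vapply(object$selections, function(s) length(s$pc_indices), 0L)
  svs <- vapply(object$models, function(m) nrow(m$support_vectors), 0L)
  cv <- vapply(object$models, function(m) max(m$cv_summary$mean_auroc), 0)
  out <- data.frame(class = names(object$models),
                    n_cells = as.integer(table(object$labels)[names(object$models)]),
                    informative_pcs = sel, support_vectors = svs,
                    cv_auroc = cv, row.names = NULL)
  structure(list(classes = out, threshold = object$threshold,
                 var_explained = object$eigenspace$var_explained),
            class = "summary.eigencell")
}

#' @export
print.summary.eigencell <- function(x, ...) {
  cat("eigencell model summary\n")
  print(x$classes, row.names = FALSE)
  cat(sprintf("rejection threshold %g; %d components retaining %.1f%% variance\n",
              x$threshold, length(x$var_explained),
              100 * sum(x$var_explained)))
  invisible(x)
}

#' @export
coef.eigencell <- function(object, ...) {
  lapply(object$models, function(m)
    list(kernel_sigma = m$kernel_sigma, cost = m$cost,
         intercept = m$intercept, platt_a = m$platt_a,
         platt_b = m$platt_b, n_support_vectors = nrow(m$support_vectors)))
}

#' Training-score plot
#'
#' Scatter of the training cells on two principal components, coloured
#' by class.
#'
#' @param x a fitted [eigencell()] model.
#' @param pcs the two PCs to draw (default the first two retained).
#' @param ... passed to [plot.default()].
#' @export
plot.eigencell <- function(x, pcs = c(1, 2), ...) {
  s <- x$eigenspace$scores[, pcs, drop = FALSE]
  cls <- factor(x$labels)
  cols <- hcl.colors(nlevels(cls), "Dark 3")
  plot.default(s[, 1], s[, 2], col = cols[as.integer(cls)], pch = 16,
               xlab = sprintf("PC%d (%.1f%%)", pcs[1],
                              100 * x$eigenspace$var_explained[pcs[1]]),
               ylab = sprintf("PC%d (%.1f%%)", pcs[2],
                              100 * x$eigenspace$var_explained[pcs[2]]),
               ...)
  legend("topright", legend = levels(cls), col = cols, pch = 16, bty = "n")
  invisible(x)
}
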