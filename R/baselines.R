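#' Baseline predictors
#'
#' Reference predictors used to quantify what the informative-PC SVM
#' adds over simpler decision rules:
#' \describe{
#'   \item{`intercept_only`}{every cell receives the fitted hyperplane
#'     intercept as its decision value, so ranking is uninformative
#'     (AUROC 0.5 by the tie convention); exposes any class-proportion
#'     bias.}
#'   \item{`unit_coefficients`}{decision = unweighted sum of the
#'     informative-PC scores plus the fitted intercept.}
#'   \item{`all_pcs`}{a tuned SVM on every computed PC, skipping both
#'     the variance filter and the rank-sum selection.}
#'   \item{`mean_logcpm`}{a tuned SVM on the single per-cell mean of
#'     log2(CPM + 1).}
#'   \item{`de_genes`}{a rank-sum differential-expression screen on
#'     genes (BH-adjusted p < `de_alpha`, |log2 fold change| >
#'     `lfc_threshold`) followed by a tuned SVM on the selected genes'
#'     log-CPM values.}
#' }
#'
#' @param mode one of the five baseline modes.
#' @param counts training [cell_matrix()] with raw counts.
#' @param labels per-cell class labels aligned with `counts`.
#' @param positive_class the class treated as positive.
#' @param n_components,var_threshold,alpha eigenspace and PC-selection
#'   parameters (eigenspace modes only).
#' @param folds,grid,seed SVM tuning parameters.
#' @param de_alpha,lfc_threshold differential-expression screen
#'   parameters (`de_genes` mode).
#' @return An object of class `baseline_model` with a
#'   [predict.baseline_model()] method returning decision values and
#'   calibrated probabilities.
#' @export
train_baseline <- function(mode = c("intercept_only", "unit_coefficients",
                                    "all_pcs", "mean_logcpm", "de_genes"),
                           counts, labels, positive_class,
                           n_components = NULL, var_threshold = 1e-4,
                           alpha = 0.05, folds = 10, grid = NULL, seed = 1,
                           de_alpha = 0.05, lfc_threshold = 1) {
  mode <- match.arg(mode)
  stopifnot(is(counts, "cell_matrix"))
  y <- as.character(labels) == positive_class
  if (!any(y) || all(y)) stop("positive class must split the labels")
  logm <- normalize_log_cpm(counts)
  scaling <- fit_center_scale(logm)
  out <- list(mode = mode, positive_class = positive_class,
              scaling = scaling)

  if (mode %in% c("intercept_only", "unit_coefficients", "all_pcs")) {
    scaled <- apply_center_scale(logm, scaling)
    space <- fit_eigenspace(scaled, n_components)
    out$space <- space
    if (mode == "all_pcs") {
      feats <- score_matrix(space$scores,
                            seq_along(space$singular_values),
                            space$cell_ids)
      out$pc_indices <- feats$pc_indices
      out$svm <- tune_and_train_svm(feats, y, folds = folds, grid = grid,
                                    seed = seed,
                                    class_name = positive_class)
    } else {
      rfil <- filter_by_variance(space, var_threshold)
      sel <- select_informative_pcs(rfil, labels, positive_class, alpha)
      pcs <- sort(sel$pc_indices)
      if (length(pcs) == 0) stop("no informative PCs for the baseline")
      out$pc_indices <- pcs
      feats <- space$scores[, pcs, drop = FALSE]
      if (mode == "intercept_only") {
        g <- grid %||% default_svm_grid(feats, seed = seed)
        fit <- fit_rbf_svm(feats, y, g$sigma[[1]], 1)
        out$intercept <- fit$intercept
      } else {
        fit <- tune_and_train_svm(feats, y, folds = folds, grid = grid,
                                  seed = seed, class_name = positive_class)
        out$intercept <- fit$intercept
        dec <- rowSums(feats) + out$intercept
        pl <- fit_platt_scaling(dec, y)
        out$platt_a <- unname(pl["platt_a"])
        out$platt_b <- unname(pl["platt_b"])
      }
    }
  } else if (mode == "mean_logcpm") {
    feats <- matrix(Matrix::rowMeans(logm$values), ncol = 1,
                    dimnames = list(logm$cell_ids, "mean_logcpm"))
    out$svm <- tune_and_train_svm(feats, y, folds = folds, grid = grid,
                                  seed = seed, class_name = positive_class)
  } else { # de_genes
    v <- as.matrix(logm$values)
    p <- apply(v, 2, function(col) rank_sum_test(col[y], col[!y]))
    lfc <- colMeans(v[y, , drop = FALSE]) - colMeans(v[!y, , drop = FALSE])
    keep <- bh_adjust(p) < de_alpha & abs(lfc) > lfc_threshold
    if (!any(keep))
      stop("no differentially expressed genes at adjusted p < ", de_alpha,
           " and |log2 FC| > ", lfc_threshold,
           "; the de_genes baseline cannot be trained")
    out$genes <- logm$gene_ids[keep]
    out$svm <- tune_and_train_svm(v[, keep, drop = FALSE], y, folds = folds,
                                  grid = grid, seed = seed,
                                  class_name = positive_class)
  }
  structure(out, class = "baseline_model")
}

#' Score new cells with a baseline predictor
#'
#' @param object a [train_baseline()] model.
#' @param newdata a raw-count [cell_matrix()].
#' @param ... unused.
#' @return Data frame with `cell_id`, `decision` and (where the mode is
#'   probability-calibrated) `probability`.
#' @export
predict.baseline_model <- function(object, newdata, ...) {
  stopifnot(is(newdata, "cell_matrix"))
  logm <- normalize_log_cpm(newdata)
  dec <- switch(object$mode,
    intercept_only = rep(object$intercept, length(logm$cell_ids)),
    unit_coefficients = {
      scaled <- apply_center_scale(logm, object$scaling)
      p <- project_cells(scaled, object$space, object$pc_indices)
      rowSums(p$values) + object$intercept
    },
    all_pcs = {
      scaled <- apply_center_scale(logm, object$scaling)
      p <- project_cells(scaled, object$space, object$pc_indices)
      svm_decision(object$svm, p$values)
    },
    mean_logcpm = {
      feats <- matrix(Matrix::rowMeans(logm$values), ncol = 1)
      svm_decision(object$svm, feats)
    },
    de_genes = {
      hit <- match(object$genes, logm$gene_ids)
      if (anyNA(hit)) stop("test data is missing ", sum(is.na(hit)),
                           " of the baseline's genes")
      svm_decision(object$svm, as.matrix(logm$values[, hit, drop = FALSE]))
    })
  out <- data.frame(cell_id = logm$cell_ids, decision = dec)
  if (!is.null(object$svm)) {
    out$probability <- platt_probability(object$svm, dec)
  } else if (!is.null(object$platt_a)) {
    out$probability <- 1 / (1 + exp(object$platt_a * dec + object$platt_b))
  }
  out
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("<baseline_model> mode '%s', positive class '%s'\n",
              x$mode, x$positive_class))
  invisible(x)
}
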