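#' Rejection-aware confusion metrics
#'
#' Sensitivity is the proportion of true positive cells assigned the
#' positive class; cells of the positive class left `"Unassigned"` count
#' against sensitivity (they stay in the denominator).  Specificity is
#' the analogous proportion of true negative cells assigned some class
#' other than the positive one, with unassigned negatives counted as
#' incorrect.  Precision is TP / (TP + FP) and F1 the harmonic mean of
#' precision and sensitivity.
#'
#' @param pred predicted labels: a character vector (possibly containing
#'   `"Unassigned"`) or a prediction data frame with a
#'   `predicted_label` column.
#' @param truth true labels, same cells and order.
#' @param positive_class the class evaluated as positive.
#' @return An object of class `metrics_report`: list of `counts`
#'   (TP, FP, TN, FN, unassigned_pos, unassigned_neg) and the rates.
#' @export
confusion_with_rejection <- function(pred, truth, positive_class) {
  if (is.data.frame(pred)) pred <- pred$predicted_label
  pred <- as.character(pred)
  truth <- as.character(truth)
  if (length(pred) != length(truth))
    stop("pred and truth must cover identical cells")
  if (!positive_class %in% truth)
    stop("positive class '", positive_class, "' absent from truth")
  pos <- truth == positive_class
  una <- pred == "Unassigned"
  counts <- c(TP = sum(pos & pred == positive_class),
              FP = sum(!pos & pred == positive_class),
              TN = sum(!pos & pred != positive_class & !una),
              FN = sum(pos & pred != positive_class & !una),
              unassigned_pos = sum(pos & una),
              unassigned_neg = sum(!pos & una))
  sens <- counts[["TP"]] / sum(pos)
  spec <- counts[["TN"]] / sum(!pos)
  prec <- if (counts[["TP"]] + counts[["FP"]] > 0)
    counts[["TP"]] / (counts[["TP"]] + counts[["FP"]]) else NA_real_
  f1 <- if (!is.na(prec) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else 0
  structure(list(positive_class = positive_class, counts = counts,
                 sensitivity = sens, specificity = spec,
                 precision = prec, f1 = f1,
                 accuracy = (counts[["TP"]] + counts[["TN"]]) / length(truth)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> positive class '%s'\n", x$positive_class))
  print(x$counts)
  cat(sprintf("  sensitivity %.4f  specificity %.4f  precision %s  F1 %.4f\n",
              x$sensitivity, x$specificity,
              ifelse(is.na(x$precision), "NA", sprintf("%.4f", x$precision)),
              x$f1))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Probability-of-concordance estimate: the probability that a random
#' positive cell scores above a random negative cell, with ties counted
#' one half (equivalent to trapezoidal integration of the ROC curve).
#'
#' @param scores numeric scores, higher meaning more positive.
#' @param truth logical (or coercible) vector, `TRUE` for positives.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, truth) {
  y <- as.logical(truth)
  if (length(scores) != length(y)) stop("lengths differ")
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)                     # midranks handle ties as 1/2
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) integration over the distinct score
#' thresholds, descending: `sum over thresholds of precision * (recall
#' increment)`.  For a constant score this gives the class prevalence.
#'
#' @param scores numeric scores, higher meaning more positive.
#' @param truth logical (or coercible) vector with at least one
#'   positive.
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, truth) {
  y <- as.logical(truth)
  if (length(scores) != length(y)) stop("lengths differ")
  n_pos <- sum(y)
  if (n_pos == 0) stop("no positive cells")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  grp <- cumsum(!duplicated(s))         # tie group per distinct threshold
  tp <- cumsum(yy); fp <- cumsum(!yy)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Repeated stratified split evaluation with percentile intervals
#'
#' Repeatedly splits the cells into a stratified training fraction and a
#' held-out test fraction, refits with `fit_predict`, and summarises
#' each class's rejection-aware metrics by their mean and percentile
#' 2.5%/97.5% bounds across replicates.  A replicate whose partition
#' loses a class entirely is redrawn (at most 10 attempts).
#'
#' @param counts a raw-count [cell_matrix()].
#' @param labels per-cell class labels.
#' @param fit_predict function `(train_counts, train_labels,
#'   test_counts) -> predicted labels` (a character vector or a data
#'   frame with `predicted_label`).  Defaults to the full [eigencell()]
#'   pipeline with arguments passed through `...`.
#' @param n_replicates number of replicates (default 10).
#' @param split_frac training fraction (default 0.75).
#' @param seed RNG seed; the same seed reproduces the same partitions,
#'   so competing methods can be scored on identical splits.
#' @param ... passed to [eigencell()] by the default `fit_predict`.
#' @return List with `replicates` (long data frame: replicate, class,
#'   metric, value) and `summary` (per class and metric: mean, lower,
#'   upper).
#' @export
bootstrap_evaluate <- function(counts, labels, fit_predict = NULL,
                               n_replicates = 10, split_frac = 0.75,
                               seed = 1, ...) {
  stopifnot(is(counts, "cell_matrix"))
  if (n_replicates < 2) stop("need at least 2 replicates")
  labels <- as.character(labels)
  if (is.null(fit_predict)) {
    dots <- list(...)
    fit_predict <- function(trc, trl, tec) {
      fit <- do.call(eigencell, c(list(counts = trc, labels = trl), dots))
      predict(fit, tec)
    }
  }
  classes <- sort(unique(labels))
  rows <- list()
  for (r in seq_len(n_replicates)) {
    tr_idx <- NULL
    for (attempt in 1:10) {
      cand <- with_seed(seed * 1000L + r * 10L + attempt, {
        unlist(lapply(classes, function(cl) {
          idx <- which(labels == cl)
          sample(idx, max(1, round(split_frac * length(idx))))
        }))
      })
      if (length(unique(labels[cand])) == length(classes) &&
          length(unique(labels[-cand])) == length(classes)) {
        tr_idx <- sort(cand)
        break
      }
    }
    if (is.null(tr_idx)) stop("could not draw a non-degenerate split")
    pred <- fit_predict(cm_subset(counts, cells = tr_idx),
                        labels[tr_idx],
                        cm_subset(counts, cells = -tr_idx))
    if (is.data.frame(pred)) pred <- pred$predicted_label
    te_lab <- labels[-tr_idx]
    for (cl in classes) {
      m <- confusion_with_rejection(pred, te_lab, cl)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, class = cl,
        metric = c("sensitivity", "specificity", "precision", "f1"),
        value = c(m$sensitivity, m$specificity, m$precision, m$f1))
    }
  }
  rep_df <- do.call(rbind, rows)
  agg <- aggregate(value ~ class + metric, rep_df, function(v)
    c(mean = mean(v), lower = unname(quantile(v, 0.025, na.rm = TRUE)),
      upper = unname(quantile(v, 0.975, na.rm = TRUE))))
  summary <- cbind(agg[c("class", "metric")], as.data.frame(agg$value))
  list(replicates = rep_df, summary = summary)
}

#' Downsample reads per cell
#'
#' Thins each cell whose total exceeds `target_per_cell` to exactly that
#' total by multivariate hypergeometric (without-replacement) sampling
#' of its reads; cells at or below the target are unchanged.
#'
#' @param counts a raw-count [cell_matrix()].
#' @param target_per_cell target total per cell (>= 1).
#' @param seed RNG seed.
#' @return A `cell_matrix` of downsampled integer counts.
#' @export
downsample_reads <- function(counts, target_per_cell, seed = 1) {
  stopifnot(is(counts, "cell_matrix"))
  if (counts$unit != "counts") stop("downsample_reads expects raw counts")
  if (target_per_cell < 1) stop("target_per_cell must be >= 1")
  v <- as.matrix(counts$values)
  with_seed(seed, {
    for (i in seq_len(nrow(v))) {
      tot <- sum(v[i, ])
      if (tot <= target_per_cell) next
      want <- target_per_cell
      left <- tot
      nz <- which(v[i, ] > 0)
      new <- numeric(length(nz))
      for (j in seq_along(nz)) {
        cj <- v[i, nz[j]]
        x <- rhyper(1, cj, left - cj, want)
        new[j] <- x
        want <- want - x
        left <- left - cj
        if (want == 0) break
      }
      v[i, ] <- 0
      v[i, nz] <- new
    }
  })
  cell_matrix(v, counts$cell_ids, counts$gene_ids, unit = "counts")
}
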