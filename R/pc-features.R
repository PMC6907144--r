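#' Two-tailed Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided p value for a location difference between two independent
#' samples.  When both groups have at most 8 observations and there are
#' no ties the exact null distribution of the Mann-Whitney U statistic
#' is used; otherwise the normal approximation with tie correction and a
#' continuity correction.
#'
#' @param group_a,group_b numeric vectors, both non-empty.
#' @return A single p value in (0, 1].
#' @export
rank_sum_test <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty")
  if (!all(is.finite(c(group_a, group_b)))) stop("non-finite values")
  n <- length(group_a)
  m <- length(group_b)
  r <- rank(c(group_a, group_b))
  u <- sum(r[seq_len(n)]) - n * (n + 1) / 2       # Mann-Whitney U of group A
  ties <- table(r)
  if (n <= 8 && m <= 8 && !any(ties > 1)) {
    p <- if (u > n * m / 2)
      2 * (1 - pwilcox(u - 1, n, m))
    else
      2 * pwilcox(u, n, m)
    return(min(1, p))
  }
  mu <- n * m / 2
  sig2 <- (n * m / 12) *
    ((n + m + 1) - sum(ties^3 - ties) / ((n + m) * (n + m - 1)))
  if (sig2 <= 0) return(1)                        # all observations tied
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2) # continuity-corrected
  max(min(2 * pnorm(-abs(z)), 1), .Machine$double.xmin)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p values, order-preserving with
#' the input and capped at 1.
#'
#' @param p_values numeric vector of p values in \[0, 1\].
#' @return Adjusted p values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) && (any(!is.finite(p_values)) ||
                           any(p_values < 0 | p_values > 1)))
    stop("p values must lie in [0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Select class-informative principal components
#'
#' For one class, tests every PC column of `scores` with a two-tailed
#' rank-sum test of that class's cells against all remaining cells,
#' adjusts the p values with Benjamini-Hochberg over exactly those
#' tests, and keeps the PCs with adjusted p below `alpha`, ranked by
#' ascending adjusted p (ties broken by lower PC index).
#'
#' @param scores a [score_matrix()] (typically the variance-filtered
#'   training scores).
#' @param labels character or factor vector of cell classes, aligned
#'   with the rows of `scores`.
#' @param class_name the positive class.
#' @param alpha significance level on the adjusted p values
#'   (default 0.05).
#' @return An object of class `pc_selection`: list with `class_name`,
#'   `pc_indices` (selected, in ranking order), `p_raw`, `p_adj` (both
#'   named by tested PC index) and `alpha`.
#' @export
select_informative_pcs <- function(scores, labels, class_name, alpha = 0.05) {
  stopifnot(is(scores, "score_matrix"))
  labels <- as.character(labels)
  if (length(labels) != nrow(scores$values))
    stop("labels length must match the number of cells")
  in_class <- labels == class_name
  if (!any(in_class)) stop("class '", class_name, "' absent from labels")
  if (sum(in_class) < 2 || sum(!in_class) < 2)
    stop("both groups need at least 2 cells")
  p_raw <- apply(scores$values, 2, function(col)
    rank_sum_test(col[in_class], col[!in_class]))
  p_adj <- bh_adjust(p_raw)
  names(p_raw) <- names(p_adj) <- scores$pc_indices
  hit <- which(p_adj < alpha)
  if (length(hit) == 0 && alpha <= 0)
    warning("alpha = 0 selects no principal components")
  ord <- hit[order(p_adj[hit], scores$pc_indices[hit])]
  structure(list(class_name = class_name,
                 pc_indices = scores$pc_indices[ord],
                 p_raw = p_raw, p_adj = p_adj, alpha = alpha),
            class = "pc_selection")
}

#' @export
print.pc_selection <- function(x, ...) {
  cat(sprintf("<pc_selection> class '%s': %d/%d PCs at adjusted p < %g\n",
              x$class_name, length(x$pc_indices), length(x$p_adj), x$alpha))
  if (length(x$pc_indices))
    cat("  PCs:", paste(x$pc_indices, collapse = ", "), "\n")
  invisible(x)
}

#' Selection table
#'
#' @param x a [select_informative_pcs()] result.
#' @return Data frame with one row per tested PC: `pc_index`, `p_raw`,
#'   `p_adj`, `selected`.
#' @export
selection_table <- function(x) {
  stopifnot(is(x, "pc_selection"))
  idx <- as.integer(names(x$p_adj))
  data.frame(pc_index = idx, p_raw = unname(x$p_raw),
             p_adj = unname(x$p_adj), selected = idx %in% x$pc_indices)
}
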