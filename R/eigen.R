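#' Truncated SVD eigenspace of a scaled expression matrix
#'
#' Factorises the centred and scaled training matrix M as U D V' and
#' stores the rotation V, the singular values, the PC scores S = U D and
#' the fraction of variance explained by each component,
#' `d_i^2 / ||M||_F^2` (the squared-Frobenius-norm denominator counts
#' all components, not just the retained ones).  Each rotation column is
#' sign-fixed so its largest-magnitude loading is positive, removing the
#' solver-dependent sign ambiguity of the SVD.
#'
#' @param scaled a [apply_center_scale()] result built from the training
#'   data itself.
#' @param n_components number of components to retain; default
#'   `min(n_cells - 1, n_genes, 100)`.
#' @return An object of class `eigenspace`: list with `rotation`
#'   (genes x k), `singular_values`, `scores` (cells x k),
#'   `var_explained`, `total_variance`, `gene_ids`, `cell_ids`,
#'   `n_cells` and the `scaling`.
#' @export
fit_eigenspace <- function(scaled, n_components = NULL) {
  stopifnot(is(scaled, "scaled_matrix"))
  m <- scaled$values
  if (!all(is.finite(m))) stop("non-finite entries in scaled matrix")
  n <- nrow(m)
  kmax <- min(n, ncol(m))
  if (is.null(n_components)) n_components <- min(n - 1L, ncol(m), 100L)
  if (n_components < 1 || n_components > kmax)
    stop("n_components must be in [1, ", kmax, "]")
  k <- as.integer(n_components)
  dec <- svd(m, nu = k, nv = k)
  d <- dec$d[seq_len(k)]
  u <- dec$u
  v <- dec$v
  # deterministic sign: largest-|loading| entry of each rotation column > 0
  for (j in seq_len(k)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) {
      v[, j] <- -v[, j]
      u[, j] <- -u[, j]
    }
  }
  total_var <- sum(m * m)
  scores <- sweep(u, 2, d, "*")
  dimnames(v) <- list(scaled$gene_ids, paste0("PC", seq_len(k)))
  dimnames(scores) <- list(scaled$cell_ids, paste0("PC", seq_len(k)))
  structure(list(rotation = v, singular_values = d, scores = scores,
                 var_explained = d^2 / total_var, total_variance = total_var,
                 gene_ids = scaled$gene_ids, cell_ids = scaled$cell_ids,
                 n_cells = n, scaling = scaled$scaling),
            class = "eigenspace")
}

#' @export
print.eigenspace <- function(x, ...) {
  cat(sprintf("<eigenspace> %d cells, %d genes, %d components (%.1f%% variance)\n",
              x$n_cells, length(x$gene_ids), length(x$singular_values),
              100 * sum(x$var_explained)))
  invisible(x)
}

#' Filter principal components by variance explained
#'
#' Keeps the components explaining at least `min_frac` of the total
#' variance (default 0.01%), preserving their order.
#'
#' @param space an [fit_eigenspace()] result.
#' @param min_frac variance-explained threshold, in (0, 1).
#' @return An object of class `score_matrix`: list with `values`
#'   (cells x kept PCs), `pc_indices` and `cell_ids`.
#' @export
filter_by_variance <- function(space, min_frac = 1e-4) {
  stopifnot(is(space, "eigenspace"))
  if (!is.numeric(min_frac) || length(min_frac) != 1 ||
      min_frac <= 0 || min_frac >= 1)
    stop("min_frac must be in (0, 1)")
  keep <- which(space$var_explained >= min_frac)
  if (length(keep) == 0)
    stop("no principal component explains at least ",
         format(min_frac), " of the variance; lower min_frac")
  score_matrix(space$scores[, keep, drop = FALSE], keep, space$cell_ids)
}

#' Score matrix constructor
#'
#' @param values cells x k numeric matrix of PC scores.
#' @param pc_indices strictly increasing indices of the PCs the columns
#'   correspond to.
#' @param cell_ids cell identifiers.
#' @return A `score_matrix` object.
#' @export
score_matrix <- function(values, pc_indices, cell_ids = rownames(values)) {
  values <- as.matrix(values)
  pc_indices <- as.integer(pc_indices)
  if (length(pc_indices) != ncol(values))
    stop("pc_indices length must equal the number of score columns")
  if (length(pc_indices) < 1) stop("at least one PC required")
  if (is.unsorted(pc_indices, strictly = TRUE))
    stop("pc_indices must be strictly increasing")
  dimnames(values) <- list(cell_ids, paste0("PC", pc_indices))
  structure(list(values = values, pc_indices = pc_indices,
                 cell_ids = cell_ids),
            class = "score_matrix")
}

#' Project cells onto a training eigenspace
#'
#' Computes P = M_test V for the requested components, where M_test is a
#' test matrix centred and scaled with the training parameters.
#'
#' @param test_scaled an [apply_center_scale()] result produced with
#'   `space$scaling` (gene order must match the eigenspace).
#' @param space an [fit_eigenspace()] result.
#' @param pc_indices components to return (default: all in `space`).
#' @return A [score_matrix()] of projected coordinates.
#' @export
project_cells <- function(test_scaled, space, pc_indices = NULL) {
  stopifnot(is(test_scaled, "scaled_matrix"), is(space, "eigenspace"))
  if (!identical(test_scaled$gene_ids, space$gene_ids))
    stop("gene order of the scaled matrix does not match the eigenspace")
  if (is.null(pc_indices)) pc_indices <- seq_along(space$singular_values)
  pc_indices <- sort(as.integer(pc_indices))
  if (any(pc_indices < 1 | pc_indices > ncol(space$rotation)))
    stop("pc_indices out of range")
  p <- test_scaled$values %*% space$rotation[, pc_indices, drop = FALSE]
  score_matrix(p, pc_indices, test_scaled$cell_ids)
}
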