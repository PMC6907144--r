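#' Gaussian radial basis kernel
#'
#' `k(x, y) = exp(-sigma * ||x - y||^2)`.
#'
#' @param x,y numeric vectors of equal length.
#' @param sigma positive kernel width parameter.
#' @return Kernel value in (0, 1].
#' @export
rbf_kernel <- function(x, y, sigma) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  exp(-sigma * sum((x - y)^2))
}

# rows(X) x rows(Y) kernel matrix
rbf_kernel_matrix <- function(X, Y, sigma) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-sigma * pmax(d2, 0))
}

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  force(seed)     # evaluate caller RNG use before the state is saved
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# C-classification RBF SVM via the kernlab QP solver, with the decision
# function re-expressed as K(X, SV) %*% dual_coefs + intercept and
# oriented so that positive-class cells receive the larger values.
fit_rbf_svm <- function(X, y, sigma, cost) {
  X <- as.matrix(X)
  yf <- factor(ifelse(y, "pos", "neg"), levels = c("neg", "pos"))
  fit <- kernlab::ksvm(x = X, y = yf, type = "C-svc", kernel = "rbfdot",
                       kpar = list(sigma = sigma), C = cost, scaled = FALSE)
  svi <- unlist(kernlab::alphaindex(fit))
  co <- unlist(kernlab::coef(fit))
  b <- -kernlab::b(fit)
  sv <- X[svi, , drop = FALSE]
  dec <- drop(rbf_kernel_matrix(X, sv, sigma) %*% co + b)
  if (mean(dec[y]) < mean(dec[!y])) {
    co <- -co
    b <- -b
  }
  list(support_vectors = sv, dual_coefs = co, intercept = b,
       kernel_sigma = sigma, cost = cost)
}

#' Decision values of a stored SVM model
#'
#' Evaluates `f(x) = sum_i alpha_i k(x, x_i) + b` from the stored
#' support vectors, dual coefficients and intercept.
#'
#' @param model an `svm_model` (or the internal fitted list).
#' @param features numeric matrix of cells x features in the model's
#'   feature space.
#' @return Numeric vector of decision values, higher for the positive
#'   class.
#' @export
svm_decision <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != ncol(model$support_vectors))
    stop("feature dimension does not match the model's support vectors")
  drop(rbf_kernel_matrix(features, model$support_vectors,
                         model$kernel_sigma) %*% model$dual_coefs +
       model$intercept)
}

#' Platt probability calibration
#'
#' Fits the sigmoid `Pr(y = 1 | f) = 1 / (1 + exp(A f + B))` to decision
#' values by regularised maximum likelihood (the Lin-Weng damped Newton
#' iteration with out-of-sample target values `(n+ + 1)/(n+ + 2)` and
#' `1/(n- + 2)`).
#'
#' @param decision_values numeric decision values.
#' @param labels logical (or coercible) vector, `TRUE` for the positive
#'   class; both classes must be present.
#' @param max_iter,tol iteration cap and gradient-norm convergence
#'   tolerance.
#' @return Named numeric vector `c(platt_a, platt_b)`.
#' @export
fit_platt_scaling <- function(decision_values, labels, max_iter = 100,
                              tol = 1e-8) {
  y <- as.logical(labels)
  f <- as.numeric(decision_values)
  if (length(f) != length(y)) stop("lengths differ")
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  hi <- (n_pos + 1) / (n_pos + 2)
  lo <- 1 / (n_neg + 2)
  t <- ifelse(y, hi, lo)
  nll <- function(a, b) {
    fab <- a * f + b
    sum(ifelse(fab >= 0, t * fab + log1p(exp(-fab)),
               (t - 1) * fab + log1p(exp(fab))))
  }
  a <- 0
  b <- log((n_neg + 1) / (n_pos + 1))
  fval <- nll(a, b)
  min_step <- 1e-10
  for (it in seq_len(max_iter)) {
    fab <- a * f + b
    p <- ifelse(fab >= 0, exp(-fab) / (1 + exp(-fab)), 1 / (1 + exp(fab)))
    q <- 1 - p
    d2 <- p * q
    h11 <- sum(f * f * d2) + 1e-12
    h22 <- sum(d2) + 1e-12
    h21 <- sum(f * d2)
    d1 <- t - p
    g1 <- sum(f * d1)
    g2 <- sum(d1)
    if (max(abs(g1), abs(g2)) < tol) break
    det <- h11 * h22 - h21 * h21
    da <- -(h22 * g1 - h21 * g2) / det
    db <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * da + g2 * db
    step <- 1
    repeat {
      na <- a + step * da
      nb <- b + step * db
      nf <- nll(na, nb)
      if (nf < fval + 1e-4 * step * gd) {
        a <- na; b <- nb; fval <- nf
        break
      }
      step <- step / 2
      if (step < min_step)
        stop("Platt scaling line search failed to make progress")
    }
    if (it == max_iter && max(abs(g1), abs(g2)) >= tol)
      stop("Platt scaling did not converge in ", max_iter, " iterations")
  }
  c(platt_a = a, platt_b = b)
}

#' Sigmoid probability from decision values
#'
#' @param model an `svm_model` with Platt coefficients.
#' @param decision numeric decision values.
#' @return Probabilities in (0, 1).
#' @export
platt_probability <- function(model, decision) {
  1 / (1 + exp(model$platt_a * decision + model$platt_b))
}

#' Stratified cross-validation folds
#'
#' @param labels logical or factor vector.
#' @param k number of folds.
#' @param seed RNG seed for the within-class shuffles.
#' @return Integer fold assignment (1..k) per observation; every class
#'   is spread across folds as evenly as possible.
#' @export
stratified_folds <- function(labels, k, seed = 1) {
  labels <- as.character(labels)
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Default (sigma, cost) tuning grid
#'
#' Kernel widths are the 0.1/0.5/0.9 quantiles of the reciprocals of the
#' non-zero pairwise squared distances between cells (a median-heuristic
#' style rule); costs are powers of two from 0.25 to 16.
#'
#' @param features numeric matrix of training features.
#' @param seed RNG seed used when subsampling cells for the distance
#'   quantiles (at most 500 cells are used).
#' @return List with numeric vectors `sigma` and `cost`.
#' @export
default_svm_grid <- function(features, seed = 1) {
  X <- as.matrix(features)
  if (nrow(X) > 500)
    X <- X[with_seed(seed, sample(nrow(X), 500)), , drop = FALSE]
  d2 <- as.numeric(dist(X))^2
  d2 <- d2[d2 > 0]
  sigma <- if (length(d2) == 0) 1 else
    unname(quantile(1 / d2, c(0.1, 0.5, 0.9)))
  list(sigma = sigma, cost = c(0.25, 0.5, 1, 2, 4, 8, 16))
}

#' Tune and train a calibrated binary RBF SVM
#'
#' Runs stratified k-fold cross-validation over a (sigma, cost) grid,
#' selects the point with the highest mean validation AUROC (ties broken
#' by smaller cost, then smaller sigma), refits on all cells at the
#' chosen point and calibrates a Platt sigmoid on the out-of-fold
#' decision values of that point.
#'
#' @param features a [score_matrix()] or numeric matrix (cells x
#'   features).
#' @param labels logical vector (`TRUE` = positive class) or a
#'   two-level factor/character vector whose positive level is given by
#'   `positive`.
#' @param folds number of CV folds (default 10); reduced with a warning
#'   when the smaller class has fewer cells.
#' @param grid list with `sigma` and `cost` vectors; default
#'   [default_svm_grid()].
#' @param seed RNG seed for fold assignment and the grid heuristic.
#' @param positive positive level when `labels` is not logical.
#' @param class_name label stored on the model.
#' @return An object of class `svm_model`: `kernel_sigma`, `cost`,
#'   `support_vectors`, `dual_coefs`, `intercept`, `platt_a`, `platt_b`,
#'   `cv_summary` (per-grid-point mean AUROC) and `class_name`.
#' @export
tune_and_train_svm <- function(features, labels, folds = 10, grid = NULL,
                               seed = 1, positive = NULL,
                               class_name = positive %||% "positive") {
  X <- if (is(features, "score_matrix")) features$values else
    as.matrix(features)
  y <- binarize_labels(labels, positive)
  if (all(y) || all(!y)) stop("labels contain a single class")
  n_min <- min(sum(y), sum(!y))
  if (n_min < 2) stop("both classes need at least 2 cells")
  if (n_min < folds) {
    folds <- max(2L, n_min)
    warning("reducing folds to ", folds, " (smallest class has ",
            n_min, " cells)")
  }
  if (is.null(grid)) grid <- default_svm_grid(X, seed = seed)
  if (length(grid$sigma) == 0 || length(grid$cost) == 0)
    stop("empty tuning grid")
  pts <- expand.grid(sigma = grid$sigma, cost = grid$cost,
                     KEEP.OUT.ATTRS = FALSE)
  fold <- stratified_folds(y, folds, seed = seed)
  oof <- matrix(NA_real_, nrow(X), nrow(pts))
  auc <- matrix(NA_real_, folds, nrow(pts))
  for (f in seq_len(folds)) {
    tr <- fold != f
    for (g in seq_len(nrow(pts))) {
      m <- fit_rbf_svm(X[tr, , drop = FALSE], y[tr],
                       pts$sigma[g], pts$cost[g])
      dec <- svm_decision(m, X[!tr, , drop = FALSE])
      oof[!tr, g] <- dec
      auc[f, g] <- auroc(dec, y[!tr])
    }
  }
  mean_auc <- colMeans(auc)
  best <- order(-mean_auc, pts$cost, pts$sigma)[1]
  final <- fit_rbf_svm(X, y, pts$sigma[best], pts$cost[best])
  platt <- fit_platt_scaling(oof[, best], y)
  structure(c(final,
              list(platt_a = unname(platt["platt_a"]),
                   platt_b = unname(platt["platt_b"]),
                   cv_summary = data.frame(pts, mean_auroc = mean_auc),
                   folds = folds, class_name = class_name)),
            class = "svm_model")
}

#' @export
print.svm_model <- function(x, ...) {
  cat(sprintf(
    "<svm_model> class '%s': sigma %.4g, cost %.4g, %d support vectors\n",
    x$class_name, x$kernel_sigma, x$cost, nrow(x$support_vectors)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# logical positive-class indicator from assorted label encodings
binarize_labels <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(labels)
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (is.null(positive)) {
    if (length(lv) != 2)
      stop("non-logical labels need a 'positive' class (found ",
           length(lv), " levels)")
    positive <- lv[2]
  }
  if (!positive %in% lv) stop("positive class '", positive, "' not in labels")
  labels == positive
}

#' SMOTE oversampling of the minority class
#'
#' Generates synthetic minority cells at `x + lambda * (x_nn - x)` with
#' `lambda ~ Uniform(0, 1)` and `x_nn` one of the `k_neighbors` nearest
#' minority neighbours of `x`, until the classes are balanced.  Original
#' cells are preserved unchanged.
#'
#' @param features a [score_matrix()] or numeric matrix.
#' @param labels binary label vector (logical or two-level).
#' @param k_neighbors number of nearest neighbours (default 5; capped at
#'   minority size - 1).
#' @param seed RNG seed.
#' @return List with `features` (same type as the input, originals
#'   first) and `labels` (same encoding, extended).
#' @export
smote_oversample <- function(features, labels, k_neighbors = 5, seed = 1) {
  is_sm <- is(features, "score_matrix")
  X <- if (is_sm) features$values else as.matrix(features)
  lab <- if (is.logical(labels)) labels else as.character(labels)
  if (length(lab) != nrow(X)) stop("labels length must match rows")
  tab <- table(lab)
  if (length(tab) != 2) stop("SMOTE requires exactly two classes")
  if (tab[1] == tab[2])
    return(list(features = features, labels = labels))
  min_class <- names(tab)[which.min(tab)]
  idx_min <- which(as.character(lab) == min_class)
  n_min <- length(idx_min)
  if (n_min < 2) stop("minority class must have at least 2 cells")
  n_new <- as.integer(max(tab) - n_min)
  k <- min(k_neighbors, n_min - 1)
  Xm <- X[idx_min, , drop = FALSE]
  d <- as.matrix(dist(Xm))
  diag(d) <- Inf
  nn <- matrix(0L, n_min, k)
  for (i in seq_len(n_min)) nn[i, ] <- order(d[i, ])[seq_len(k)]
  synth <- with_seed(seed, {
    base <- sample(n_min, n_new, replace = TRUE)
    pick <- nn[cbind(base, sample(k, n_new, replace = TRUE))]
    lam <- runif(n_new)
    Xm[base, , drop = FALSE] +
      lam * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
  })
  rownames(synth) <- paste0("smote_", seq_len(n_new))
  out <- rbind(X, synth)
  new_lab <- if (is.logical(labels))
    c(labels, rep(min_class == "TRUE", n_new))
  else c(labels, rep(min_class, n_new))
  feats <- if (is_sm)
    score_matrix(out, features$pc_indices, rownames(out))
  else out
  list(features = feats, labels = new_lab)
}
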