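test_that("RBF kernel matches its closed form and is symmetric", {
  set.seed(41)
  x <- rnorm(5); y <- rnorm(5)
  expect_equal(rbf_kernel(x, x, 2), 1)
  expect_equal(rbf_kernel(c(0, 0), c(1, 0), 1), exp(-1))
  for (i in 1:5) {
    a <- rnorm(4); b <- rnorm(4); s <- runif(1, 0.1, 3)
    expect_equal(rbf_kernel(a, b, s), rbf_kernel(b, a, s))
    expect_equal(rbf_kernel(a, b, s), exp(-s * sum((a - b)^2)))
  }
  expect_error(rbf_kernel(1:3, 1:2, 1), "equal length")
  expect_error(rbf_kernel(1:3, 1:3, -1), "positive")
})

test_that("stored SVM parameters reproduce the solver's decision values", {
  set.seed(42)
  x <- rbind(matrix(rnorm(60, 1.5), 30, 2), matrix(rnorm(60, -1.5), 30, 2))
  y <- rep(c(TRUE, FALSE), each = 30)
  fit <- eigencell:::fit_rbf_svm(x, y, sigma = 0.5, cost = 2)
  dec <- svm_decision(fit, x)
  # oracle: kernlab's own decision values (orientation-insensitive)
  ref <- kernlab::ksvm(x, factor(ifelse(y, "pos", "neg"),
                                 levels = c("neg", "pos")),
                       type = "C-svc", kernel = "rbfdot",
                       kpar = list(sigma = 0.5), C = 2, scaled = FALSE)
  refdec <- as.numeric(kernlab::predict(ref, x, type = "decision"))
  expect_equal(abs(dec), abs(refdec), tolerance = 1e-8)
  # orientation: positives high
  expect_gt(mean(dec[y]), mean(dec[!y]))
  # box constraint on dual coefficients
  expect_true(all(abs(fit$dual_coefs) <= 2 + 1e-8))
})

test_that("Platt sigmoid has the stated closed form", {
  m <- list(platt_a = -1, platt_b = 0)
  expect_equal(platt_probability(m, 0), 0.5)
  m2 <- list(platt_a = -2, platt_b = 0)
  expect_equal(platt_probability(m2, 1), 1 / (1 + exp(-2)))
})

test_that("Platt fit separates well-separated decision values", {
  set.seed(43)
  f <- c(runif(100, -3, -1), runif(100, 1, 3))
  y <- rep(c(FALSE, TRUE), each = 100)
  pl <- fit_platt_scaling(f, y)
  p <- 1 / (1 + exp(pl["platt_a"] * f + pl["platt_b"]))
  expect_true(all(p[y] > 0.9))
  expect_true(all(p[!y] < 0.1))
  # probabilities strictly monotone in the decision value
  grid <- seq(-3, 3, length.out = 50)
  pg <- 1 / (1 + exp(pl["platt_a"] * grid + pl["platt_b"]))
  expect_true(all(diff(pg) > 0))
  expect_error(fit_platt_scaling(f, rep(TRUE, 200)), "both classes")
})

test_that("cross-validated tuning separates Gaussian clouds deterministically", {
  set.seed(7)
  x <- rbind(matrix(rnorm(100, 3), 50, 2), matrix(rnorm(100, -3), 50, 2))
  y <- rep(c(TRUE, FALSE), each = 50)
  m1 <- tune_and_train_svm(x, y, folds = 5, seed = 7)
  dec <- svm_decision(m1, x)
  expect_equal(mean((dec > 0) == y), 1)          # training accuracy 1.0
  expect_gte(max(m1$cv_summary$mean_auroc), 0.99)
  m2 <- tune_and_train_svm(x, y, folds = 5, seed = 7)
  expect_identical(c(m2$kernel_sigma, m2$cost), c(m1$kernel_sigma, m1$cost))
  expect_identical(svm_decision(m2, x), dec)
  expect_error(tune_and_train_svm(x, rep(TRUE, 100)), "single class")
  expect_error(tune_and_train_svm(x, y, grid = list(sigma = numeric(0),
                                                    cost = 1)), "empty")
})

test_that("folds are stratified, exhaustive and never self-evaluating", {
  y <- rep(c("a", "b"), c(60, 30))
  f <- stratified_folds(y, 5, seed = 3)
  expect_setequal(unique(f), 1:5)
  for (k in 1:5) {
    expect_equal(sum(f == k & y == "a"), 12)
    expect_equal(sum(f == k & y == "b"), 6)
  }
  expect_identical(stratified_folds(y, 5, seed = 3), f)
})

test_that("small classes shrink the fold count with a warning", {
  set.seed(44)
  x <- matrix(rnorm(40), 20, 2)
  y <- rep(c(TRUE, FALSE), c(4, 16))
  expect_warning(m <- tune_and_train_svm(x, y, folds = 10, seed = 1,
                                         grid = list(sigma = 1, cost = 1)),
                 "reducing folds")
  expect_equal(m$folds, 4)
})

test_that("SMOTE interpolates on minority segments and balances counts", {
  # minority of two points: every synthetic point lies on their segment
  feats <- rbind(matrix(rnorm(40, 5), 20, 2),
                 matrix(c(0, 2, 0, 2), 2, 2))
  lab <- rep(c("maj", "min"), c(20, 2))
  out <- smote_oversample(feats, lab, k_neighbors = 1, seed = 9)
  expect_equal(sum(out$labels == "min"), 20)
  expect_equal(out$features[1:22, ], feats, ignore_attr = TRUE)
  synth <- out$features[-(1:22), , drop = FALSE]
  expect_equal(synth[, 1], synth[, 2], tolerance = 1e-12,
               ignore_attr = TRUE)                      # on the diagonal
  expect_true(all(synth >= -1e-12 & synth <= 2 + 1e-12))
  # balanced input is returned unchanged
  bal <- smote_oversample(feats[1:4, ], rep(c("a", "b"), 2), seed = 1)
  expect_identical(bal$features, feats[1:4, ])
  # determinism and ratio for a 1:5 imbalance
  set.seed(45)
  f2 <- matrix(rnorm(120 * 3), 120, 3)
  l2 <- rep(c(TRUE, FALSE), c(20, 100))
  o1 <- smote_oversample(f2, l2, seed = 11)
  o2 <- smote_oversample(f2, l2, seed = 11)
  expect_identical(o1, o2)
  ratio <- sum(o1$labels) / sum(!o1$labels)
  expect_true(ratio >= 0.9 && ratio <= 1.1)
  expect_error(smote_oversample(f2[1:101, ], rep(c(TRUE, FALSE), c(1, 100))),
               "at least 2")
})

test_that("every SMOTE point is a convex combination of two minority cells", {
  set.seed(46)
  f <- matrix(rnorm(60 * 2), 60, 2)
  l <- rep(c(TRUE, FALSE), c(15, 45))
  out <- smote_oversample(f, l, seed = 2)
  minority <- f[l, , drop = FALSE]
  synth <- out$features[-(1:60), , drop = FALSE]
  seg_dist <- function(p, a, b) {
    ab <- b - a
    t <- sum((p - a) * ab) / sum(ab * ab)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (a + t * ab))^2))
  }
  for (i in seq_len(nrow(synth))) {
    dmin <- Inf
    for (a in 1:14) for (b in (a + 1):15)
      dmin <- min(dmin, seg_dist(synth[i, ], minority[a, ], minority[b, ]))
    expect_lt(dmin, 1e-10)
  }
})

test_that("baseline predictors behave as designed", {
  sim <- small_sim()
  # intercept-only: constant decision, AUROC exactly 0.5
  b0 <- train_baseline("intercept_only", sim$counts, sim$labels, "classA")
  sc <- predict(b0, sim$counts)
  expect_equal(length(unique(sc$decision)), 1L)
  expect_identical(auroc(sc$decision, sim$labels == "classA"), 0.5)
  # mean-logcpm baseline: a class whose expression concentrates in few
  # genes has a different per-cell mean of log2(CPM + 1); a uniform
  # scaling of all genes would vanish under CPM normalisation
  set.seed(47)
  n <- 60; g <- 80
  mu_hi <- rep(c(200, 2), c(20, 60))
  mu_lo <- rep(20, g)
  shift <- rbind(t(replicate(n / 2, rnbinom(g, mu = mu_hi, size = 2))),
                 t(replicate(n / 2, rnbinom(g, mu = mu_lo, size = 2))))
  cm <- cell_matrix(shift, paste0("c", 1:n), paste0("g", 1:g))
  lab <- rep(c("hi", "lo"), each = n / 2)
  bm <- train_baseline("mean_logcpm", cm, lab, "hi", folds = 3,
                       grid = list(sigma = c(0.5, 2), cost = c(1, 4)))
  scm <- predict(bm, cm)
  expect_gt(auroc(scm$decision, lab == "hi"), 0.9)
  # de_genes on null data refuses to train
  set.seed(48)
  null <- cell_matrix(matrix(rnbinom(n * g, mu = 20, size = 2), n, g),
                      paste0("c", 1:n), paste0("g", 1:g))
  expect_error(train_baseline("de_genes", null, lab, "hi"),
               "no differentially expressed genes")
})
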