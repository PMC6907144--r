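test_that("rejection-aware confusion counts match the definitions", {
  # 100 positives: 90 correct, 4 wrong class, 6 unassigned; 50 negatives
  truth <- rep(c("pos", "neg"), c(100, 50))
  pred <- c(rep("pos", 90), rep("neg", 4), rep("Unassigned", 6),
            rep("neg", 44), rep("pos", 6))
  m <- confusion_with_rejection(pred, truth, "pos")
  expect_equal(m$sensitivity, 0.90)
  expect_equal(unname(m$counts["unassigned_pos"]), 6)
  expect_equal(m$counts[["TP"]] + m$counts[["FN"]] +
                 m$counts[["unassigned_pos"]], 100)
  # F1 by hand: precision 90/96, sensitivity 0.9
  prec <- 90 / 96
  expect_equal(m$precision, prec)
  expect_equal(m$f1, 2 * prec * 0.9 / (prec + 0.9))
  expect_error(confusion_with_rejection(pred, truth, "other"), "absent")
})

test_that("total rejection zeroes both sensitivity and specificity", {
  truth <- rep(c("pos", "neg"), c(30, 20))
  pred <- rep("Unassigned", 50)
  m <- confusion_with_rejection(pred, truth, "pos")
  expect_equal(m$sensitivity, 0)
  expect_equal(m$specificity, 0)
})

test_that("AUROC matches pair counting and is rank-invariant", {
  expect_equal(auroc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  pair_count_auroc <- function(s, y) {
    sp <- s[y]; sn <- s[!y]
    acc <- 0
    for (a in sp) for (b in sn)
      acc <- acc + (a > b) + 0.5 * (a == b)
    acc / (length(sp) * length(sn))
  }
  set.seed(61)
  for (i in 1:10) {
    s <- sample(1:8, 20, replace = TRUE)  # ties on purpose
    y <- rbinom(20, 1, 0.5) == 1
    if (all(y) || all(!y)) next
    a <- auroc(s, y)
    expect_equal(a, pair_count_auroc(s, y), tolerance = 1e-12)
    # invariant under a strictly monotone transform
    expect_equal(auroc(exp(s / 2), y), a, tolerance = 1e-12)
  }
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(62)
  s <- rnorm(50)
  y <- rbinom(50, 1, plogis(s)) == 1
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
  expect_equal(auroc(s, y), ref, tolerance = 1e-10)
})

test_that("AUPRC follows the stepwise threshold-sweep convention", {
  expect_equal(auprc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  # constant scores: a single threshold admits everything, area = prevalence
  y <- rep(c(TRUE, FALSE), c(3, 7))
  expect_equal(auprc(rep(0.5, 10), y), 0.3)
  # exhaustive threshold-sweep oracle
  sweep_auprc <- function(s, y) {
    th <- sort(unique(s), decreasing = TRUE)
    rec <- prec <- numeric(length(th))
    for (i in seq_along(th)) {
      called <- s >= th[i]
      rec[i] <- sum(called & y) / sum(y)
      prec[i] <- sum(called & y) / sum(called)
    }
    sum(diff(c(0, rec)) * prec)
  }
  set.seed(63)
  for (i in 1:10) {
    s <- sample(1:6, 15, replace = TRUE)
    y <- rbinom(15, 1, 0.4) == 1
    if (!any(y)) next
    expect_equal(auprc(s, y), sweep_auprc(s, y), tolerance = 1e-12)
  }
  expect_error(auprc(1:3, rep(FALSE, 3)), "no positive")
})

test_that("split evaluation is deterministic and summarises known accuracy", {
  sim <- small_sim()
  # stub predictor with known behaviour: flips 10% of labels to the other
  # class, deterministically by position
  stub <- function(trc, trl, tec) {
    cls <- sort(unique(trl))
    truth <- small_sim()$labels[tec$cell_ids]
    out <- truth
    flip <- seq_along(out) %% 10 == 0
    out[flip] <- ifelse(truth[flip] == cls[1], cls[2], cls[1])
    unname(out)
  }
  r1 <- bootstrap_evaluate(sim$counts, sim$labels, fit_predict = stub,
                           n_replicates = 5, seed = 3)
  r2 <- bootstrap_evaluate(sim$counts, sim$labels, fit_predict = stub,
                           n_replicates = 5, seed = 3)
  expect_identical(r1, r2)
  sens <- subset(r1$summary, metric == "sensitivity" & class == "classA")
  expect_gt(sens$mean, 0.8)
  expect_true(sens$lower <= sens$mean && sens$mean <= sens$upper)
  # constant metric across replicates has zero-width interval
  perfect <- function(trc, trl, tec) unname(small_sim()$labels[tec$cell_ids])
  rp <- bootstrap_evaluate(sim$counts, sim$labels, fit_predict = perfect,
                           n_replicates = 4, seed = 1)
  expect_true(all(rp$summary$lower == rp$summary$upper))
  expect_true(all(rp$summary$mean == 1))
  expect_error(bootstrap_evaluate(sim$counts, sim$labels,
                                  fit_predict = perfect, n_replicates = 1),
               "2 replicates")
})

test_that("read downsampling hits the target exactly and in expectation", {
  v <- matrix(c(10, 30, 60), 1, 3)
  cm <- cell_matrix(v, "c1", paste0("g", 1:3))
  set.seed(64)
  totals <- replicate(1000, {
    out <- downsample_reads(cm, 10, seed = sample.int(1e6, 1))
    as.numeric(out$values)
  })
  expect_true(all(colSums(totals) %% 1 == 0))
  expect_equal(unname(rowSums(totals) / 1000), c(1, 3, 6), tolerance = 0.1)
  one <- downsample_reads(cm, 10, seed = 5)
  expect_equal(sum(one$values), 10)
  expect_true(all(one$values <= v))
  # cells at or below the target are untouched
  small <- cell_matrix(matrix(c(2, 3), 1, 2), "c1", c("g1", "g2"))
  expect_equal(as.numeric(downsample_reads(small, 10, seed = 1)$values),
               c(2, 3))
  # determinism
  expect_identical(downsample_reads(cm, 10, seed = 9),
                   downsample_reads(cm, 10, seed = 9))
})
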