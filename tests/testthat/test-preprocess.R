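test_that("3-MAD library-size filter removes the outlier cell and only it", {
  libs <- c(90, 95, 100, 100, 100, 105, 110, 10000)
  cm <- toy_counts(libs)
  # brute-force oracle: median +/- 3 * 1.4826 * median absolute deviation
  med <- median(libs)
  dev <- 1.4826 * median(abs(libs - med))
  keep_oracle <- abs(libs - med) <= 3 * dev
  expect_equal(sum(keep_oracle), 7)
  out <- qc_filter_cells(cm)
  expect_equal(length(out$cell_ids), 7)
  expect_setequal(out$cell_ids, cm$cell_ids[keep_oracle])
  rep <- attr(out, "qc_report")
  expect_false(rep$keep[8])
  expect_false(rep$pass_libsize[8])
})

test_that("a zero-MAD metric removes no cells", {
  cm <- toy_counts(rep(100, 6))
  out <- qc_filter_cells(cm)
  expect_equal(length(out$cell_ids), 6)
})

test_that("a mito pattern matching no genes removes no cells", {
  cm <- toy_counts(c(90, 100, 110, 95, 105))
  out <- qc_filter_cells(cm, mito_pattern = "^NOPE-", ribo_pattern = "^ALSONOPE")
  rep <- attr(out, "qc_report")
  expect_true(all(rep$mito_frac == 0))
  expect_true(all(rep$pass_mito))
})

test_that("QC errors on empty input and on removing everything", {
  expect_error(qc_filter_cells(cell_matrix(matrix(0, 0, 2), character(0),
                                           c("g1", "g2"))),
               "empty")
  # two extreme groups; with n_mads tiny everything fails the lib filter
  cm <- toy_counts(c(10, 10, 10000, 10000))
  expect_error(qc_filter_cells(cm, n_mads = 1e-9), "all cells")
})

test_that("iterative QC reaches a fixed point within n_cells passes", {
  set.seed(3)
  libs <- c(round(runif(30, 90, 110)), 500, 2000, 10000)
  cm <- toy_counts(libs)
  out <- qc_filter_cells(cm, iterate = TRUE)
  expect_lte(attr(out, "qc_iterations"), length(libs))
  # a further pass with the same parameters removes nothing
  again <- qc_filter_cells(out)
  expect_equal(length(again$cell_ids), length(out$cell_ids))
})

test_that("gene filters drop all-zero, rarely detected and low-CPM genes", {
  # 4 cells, each with total 1e5 counts => CPM = count * 10
  n <- 4
  filler <- "gBIG"
  v <- cbind(c(1, 1, 0, 0),      # mean CPM = 5.0 -> dropped (must exceed 5)
             c(1, 1, 1, 0),      # mean CPM = 7.5 -> kept
             c(0, 0, 0, 0),      # all zero -> dropped
             0)                  # filler set below
  v[, 4] <- 1e5 - rowSums(v)
  cm <- cell_matrix(v, paste0("c", 1:4), c("gA", "gB", "gZ", filler))
  # hand-computed CPM means
  expect_equal(mean(v[, 1] / 1e5 * 1e6), 5.0)
  expect_equal(mean(v[, 2] / 1e5 * 1e6), 7.5)
  out <- filter_genes(cm)
  expect_setequal(out$gene_ids, c("gB", filler))
})

test_that("detection-fraction rule uses the whole population", {
  # 200 cells, one gene detected in a single cell (0.5% < 1%)
  v <- matrix(0, 200, 2)
  v[, 1] <- 1000
  v[1, 2] <- 50
  cm <- cell_matrix(v, sprintf("c%03d", 1:200), c("gKeep", "gRare"))
  out <- filter_genes(cm)
  expect_equal(out$gene_ids, "gKeep")
})

test_that("log-CPM transform matches its definition", {
  cm <- cell_matrix(matrix(c(5, 5, 0), 1, 3), "c1", c("g1", "g2", "g3"))
  lg <- normalize_log_cpm(cm)
  expect_equal(lg$unit, "logCPM")
  expect_equal(as.numeric(lg$values), log2(c(5e5, 5e5, 0) + 1))
  # CPM of 1 maps to log2(2) = 1; CPM of 0 maps to 0
  cm2 <- cell_matrix(matrix(c(1, 1e6 - 1, 0), 1, 3), "c1",
                     c("g1", "g2", "g3"))
  lg2 <- normalize_log_cpm(cm2)
  expect_equal(lg2$values[1, 1], 1)
  expect_equal(lg2$values[1, 3], 0)
  expect_error(normalize_log_cpm(
    cell_matrix(matrix(c(1, 0), 2, 1), c("a", "b"), "g")), "zero total")
})

test_that("CPM rows sum to one million", {
  sim <- small_sim()
  lg <- normalize_log_cpm(sim$counts)
  cpm <- 2^as.matrix(lg$values) - 1
  expect_equal(rowSums(cpm), rep(1e6, nrow(cpm)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("centring/scaling parameters match a two-pass oracle", {
  v <- matrix(c(1, 2, 3), 3, 1, dimnames = list(c("a", "b", "c"), "g1"))
  lg <- cell_matrix(v, unit = "logCPM")
  sc <- fit_center_scale(lg)
  expect_equal(sc$mu, 2)
  expect_equal(sc$sigma, 1)
  # constant gene excluded and reported
  v2 <- cbind(v, g2 = c(5, 5, 5))
  sc2 <- fit_center_scale(cell_matrix(v2, unit = "logCPM"))
  expect_equal(sc2$gene_ids, "g1")
  expect_equal(sc2$dropped_genes, "g2")
  # random matrix against an independent two-pass loop
  set.seed(11)
  m <- matrix(abs(rnorm(100 * 50)), 100, 50,
              dimnames = list(paste0("c", 1:100), paste0("g", 1:50)))
  sc3 <- fit_center_scale(cell_matrix(m, unit = "logCPM"))
  mu_o <- sg_o <- numeric(50)
  for (j in 1:50) {
    mu_o[j] <- sum(m[, j]) / 100
    sg_o[j] <- sqrt(sum((m[, j] - mu_o[j])^2) / 99)
  }
  expect_equal(sc3$mu, mu_o, tolerance = 1e-12)
  expect_equal(sc3$sigma, sg_o, tolerance = 1e-12)
  expect_error(fit_center_scale(cell_matrix(m[1, , drop = FALSE],
                                            unit = "logCPM")), "2 cells")
})

test_that("self-scaling yields mean-zero unit-sd columns", {
  set.seed(4)
  m <- matrix(abs(rnorm(200)), 20, 10,
              dimnames = list(paste0("c", 1:20), paste0("g", 1:10)))
  lg <- cell_matrix(m, unit = "logCPM")
  sc <- fit_center_scale(lg)
  z <- apply_center_scale(lg, sc)
  expect_lt(max(abs(colMeans(z$values))), 1e-8)
  expect_lt(max(abs(apply(z$values, 2, sd) - 1)), 1e-8)
})

test_that("gene matching fills missing genes with zero and drops unknowns", {
  set.seed(5)
  m <- matrix(abs(rnorm(40)), 4, 10,
              dimnames = list(paste0("c", 1:4), paste0("g", 1:10)))
  sc <- fit_center_scale(cell_matrix(m, unit = "logCPM"))
  test <- cell_matrix(cbind(m[, 2:10], extra = 1:4), unit = "logCPM")
  z <- apply_center_scale(test, sc)
  expect_equal(z$gene_ids, sc$gene_ids)
  expect_equal(unname(z$values[, "g1"]), rep(0, 4))   # absent -> mean
  expect_false("extra" %in% z$gene_ids)               # unknown -> dropped
  # 40% overlap fails the default 50% requirement, reporting the fraction
  test2 <- cell_matrix(m[, 1:4], unit = "logCPM")
  expect_error(apply_center_scale(test2, sc), "40.0%")
})
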