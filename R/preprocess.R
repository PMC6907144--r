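#' Quality-control filtering of cells
#'
#' Removes cells more than `n_mads` median absolute deviations (scaled by
#' the usual 1.4826 consistency constant) from the median of any of three
#' per-cell summaries: total counts (library size), mitochondrial count
#' fraction and ribosomal count fraction.  A metric whose MAD is zero is
#' skipped, so a perfectly uniform metric never removes cells.
#'
#' @param counts a [cell_matrix()] with `unit = "counts"`.
#' @param mito_pattern,ribo_pattern regular expressions matched against
#'   `gene_ids` to tag mitochondrial / ribosomal genes.  A pattern
#'   matching no genes yields an all-zero fraction and removes nothing.
#' @param n_mads robust z cut-off (default 3).
#' @param iterate if `TRUE`, refilter with recomputed summaries until a
#'   fixed point is reached; default is the single pass described for the
#'   method.
#' @return The filtered `cell_matrix`.  A per-cell data frame of metric
#'   values and pass flags is attached as attribute `"qc_report"`.
#' @export
qc_filter_cells <- function(counts, mito_pattern = "^MT-",
                            ribo_pattern = "^RP[LS]", n_mads = 3,
                            iterate = FALSE) {
  stopifnot(is(counts, "cell_matrix"))
  if (counts$unit != "counts") stop("qc_filter_cells expects raw counts")
  if (length(counts$cell_ids) == 0L) stop("empty matrix")
  n_iter <- 0L
  report <- NULL
  repeat {
    n_iter <- n_iter + 1L
    lib <- as.numeric(Matrix::rowSums(counts$values))
    mito_genes <- grepl(mito_pattern, counts$gene_ids)
    ribo_genes <- grepl(ribo_pattern, counts$gene_ids)
    frac_of <- function(mask) {
      if (!any(mask)) return(rep(0, length(lib)))
      tot <- as.numeric(Matrix::rowSums(counts$values[, mask, drop = FALSE]))
      ifelse(lib > 0, tot / lib, 0)
    }
    metrics <- list(libsize = lib, mito_frac = frac_of(mito_genes),
                    ribo_frac = frac_of(ribo_genes))
    pass <- lapply(metrics, function(m) {
      md <- median(m)
      dev <- mad(m)                     # 1.4826 * median(|m - median|)
      if (dev == 0) rep(TRUE, length(m)) else abs(m - md) <= n_mads * dev
    })
    keep <- pass$libsize & pass$mito_frac & pass$ribo_frac
    report <- data.frame(cell_id = counts$cell_ids,
                         libsize = metrics$libsize,
                         mito_frac = metrics$mito_frac,
                         ribo_frac = metrics$ribo_frac,
                         pass_libsize = pass$libsize,
                         pass_mito = pass$mito_frac,
                         pass_ribo = pass$ribo_frac,
                         keep = keep, row.names = NULL)
    if (!any(keep)) stop("QC removed all cells")
    if (all(keep)) break
    counts <- cm_subset(counts, cells = which(keep))
    if (!iterate) break
  }
  attr(counts, "qc_report") <- report
  attr(counts, "qc_iterations") <- n_iter
  counts
}

#' Gene filtering
#'
#' Drops genes with zero counts everywhere, genes detected (count > 0) in
#' fewer than `min_cell_frac` of cells, and genes whose mean CPM across
#' cells is not greater than `min_mean_cpm`.  Gene order is preserved.
#'
#' @param counts a [cell_matrix()] with `unit = "counts"`.
#' @param min_cell_frac minimum detection fraction (default 1%).
#' @param min_mean_cpm genes with mean CPM at or below this are dropped
#'   (default 5).
#' @return The filtered `cell_matrix`.
#' @export
filter_genes <- function(counts, min_cell_frac = 0.01, min_mean_cpm = 5) {
  stopifnot(is(counts, "cell_matrix"))
  if (counts$unit != "counts") stop("filter_genes expects raw counts")
  n <- length(counts$cell_ids)
  detected <- as.numeric(Matrix::colSums(counts$values > 0))
  lib <- as.numeric(Matrix::rowSums(counts$values))
  if (any(lib == 0)) stop("cells with zero total counts; run QC first")
  v <- counts$values
  if (is(v, "sparseMatrix")) {
    mean_cpm <- as.numeric(Matrix::colMeans(
      Matrix::Diagonal(x = 1e6 / lib) %*% v))
  } else {
    mean_cpm <- colMeans(v / lib * 1e6)
  }
  keep <- detected > 0 & (detected / n) >= min_cell_frac &
    mean_cpm > min_mean_cpm
  if (!any(keep)) stop("gene filtering removed all genes")
  cm_subset(counts, genes = which(keep))
}

#' Counts-per-million log transformation
#'
#' Converts raw counts to `log2(CPM + 1)`, where CPM rescales every cell
#' to a library size of one million.
#'
#' @param counts a [cell_matrix()] with `unit = "counts"`.
#' @return A `cell_matrix` with `unit = "logCPM"`.
#' @export
normalize_log_cpm <- function(counts) {
  stopifnot(is(counts, "cell_matrix"))
  if (counts$unit != "counts") stop("normalize_log_cpm expects raw counts")
  lib <- as.numeric(Matrix::rowSums(counts$values))
  if (any(lib == 0)) stop("cells with zero total counts")
  v <- counts$values
  if (is(v, "sparseMatrix")) {
    v <- as(v, "CsparseMatrix")
    v <- Matrix::Diagonal(x = 1e6 / lib) %*% v
    v@x <- log2(v@x + 1)          # zero entries stay zero: log2(0 + 1) = 0
  } else {
    v <- log2(v / lib * 1e6 + 1)
  }
  dimnames(v) <- list(counts$cell_ids, counts$gene_ids)
  cell_matrix(v, counts$cell_ids, counts$gene_ids, unit = "logCPM")
}

#' Fit per-gene centring and scaling parameters
#'
#' Computes the per-gene mean and sample standard deviation (n - 1
#' denominator) of a log-CPM matrix.  Genes with zero standard deviation
#' cannot be scaled and are excluded (and recorded).
#'
#' @param log_matrix a [cell_matrix()] with `unit = "logCPM"`.
#' @return An object of class `gene_scaling`: list with `mu`, `sigma`,
#'   `gene_ids` (genes retained) and `dropped_genes`.
#' @export
fit_center_scale <- function(log_matrix) {
  stopifnot(is(log_matrix, "cell_matrix"))
  n <- length(log_matrix$cell_ids)
  if (n < 2) stop("need at least 2 cells to estimate standard deviations")
  v <- log_matrix$values
  mu <- as.numeric(Matrix::colMeans(v))
  ex2 <- as.numeric(Matrix::colMeans(v * v))
  sigma <- sqrt(pmax(ex2 - mu^2, 0) * n / (n - 1))
  ok <- sigma > 1e-12
  structure(list(mu = mu[ok], sigma = sigma[ok],
                 gene_ids = log_matrix$gene_ids[ok],
                 dropped_genes = log_matrix$gene_ids[!ok]),
            class = "gene_scaling")
}

#' @export
print.gene_scaling <- function(x, ...) {
  cat(sprintf("<gene_scaling> %d genes (%d dropped, sd = 0)\n",
              length(x$gene_ids), length(x$dropped_genes)))
  invisible(x)
}

#' Apply stored centring and scaling to a log-CPM matrix
#'
#' Matches genes by identifier to the scaling fitted on the training
#' data.  Genes present in the scaling but absent from the input receive
#' the scaled value 0 (the training gene mean); input genes unknown to
#' the scaling are dropped.  Output column order is the scaling's gene
#' order, so the matrix is conformable with the training rotation.
#'
#' @param log_matrix a [cell_matrix()] with `unit = "logCPM"`.
#' @param scaling a [fit_center_scale()] result.
#' @param min_overlap minimum fraction of scaling genes that must be
#'   present in the input (default 0.5); below it an error reports the
#'   observed overlap.
#' @return An object of class `scaled_matrix`: list with dense `values`
#'   (cells x scaling genes), `cell_ids`, `gene_ids` and the `scaling`.
#' @export
apply_center_scale <- function(log_matrix, scaling, min_overlap = 0.5) {
  stopifnot(is(log_matrix, "cell_matrix"), is(scaling, "gene_scaling"))
  hit <- match(scaling$gene_ids, log_matrix$gene_ids)
  overlap <- mean(!is.na(hit))
  if (overlap < min_overlap)
    stop(sprintf(
      "only %.1f%% of the %d training genes are present in the input (minimum %.0f%%)",
      100 * overlap, length(scaling$gene_ids), 100 * min_overlap))
  n <- length(log_matrix$cell_ids)
  out <- matrix(0, n, length(scaling$gene_ids),
                dimnames = list(log_matrix$cell_ids, scaling$gene_ids))
  present <- which(!is.na(hit))
  x <- as.matrix(log_matrix$values[, hit[present], drop = FALSE])
  out[, present] <- sweep(sweep(x, 2, scaling$mu[present], "-"),
                          2, scaling$sigma[present], "/")
  structure(list(values = out, cell_ids = log_matrix$cell_ids,
                 gene_ids = scaling$gene_ids, scaling = scaling),
            class = "scaled_matrix")
}
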