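#' Expression matrix container
#'
#' A light cells-by-genes expression matrix with unique cell and gene
#' identifiers and a declared unit.  Sparse (`Matrix::dgCMatrix`) and
#' dense base matrices are both accepted and preserved.
#'
#' @param values numeric matrix, cells in rows and genes in columns.
#' @param cell_ids character vector of unique cell identifiers.
#' @param gene_ids character vector of unique gene identifiers.
#' @param unit one of `"counts"`, `"CPM"`, `"logCPM"`.  Raw counts must
#'   be non-negative integers.
#' @return An object of class `cell_matrix`: a list with elements
#'   `values`, `cell_ids`, `gene_ids`, `unit`.
#' @export
cell_matrix <- function(values, cell_ids = rownames(values),
                        gene_ids = colnames(values), unit = "counts") {
  unit <- match.arg(unit, c("counts", "CPM", "logCPM"))
  if (is.null(cell_ids) || is.null(gene_ids))
    stop("cell_ids and gene_ids are required")
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values) || length(gene_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions: ",
         nrow(values), " x ", ncol(values), " vs ",
         length(cell_ids), " cells / ", length(gene_ids), " genes")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  vals <- if (is(values, "sparseMatrix")) values@x else values
  if (length(vals) && min(vals) < 0) stop("negative expression values")
  if (unit == "counts" && length(vals) && any(vals != round(vals)))
    stop("unit 'counts' requires integer-valued entries")
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = cell_ids,
                 gene_ids = gene_ids, unit = unit),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf("<cell_matrix> %d cells x %d genes [%s]\n",
              length(x$cell_ids), length(x$gene_ids), x$unit))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$values)

# dense base-matrix view, used by the linear-algebra stages
cm_dense <- function(x) {
  v <- x$values
  if (is(v, "sparseMatrix")) v <- as.matrix(v)
  storage.mode(v) <- "double"
  v
}

# subset keeping class and metadata consistent
cm_subset <- function(x, cells = NULL, genes = NULL) {
  v <- x$values
  if (!is.null(cells)) v <- v[cells, , drop = FALSE]
  if (!is.null(genes)) v <- v[, genes, drop = FALSE]
  cell_matrix(v, rownames(v), colnames(v), unit = x$unit)
}
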