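#' Read an expression matrix from disk
#'
#' Accepts either Matrix Market coordinate format with sidecar
#' identifier files (the CellRanger convention: genes as rows, cells as
#' columns, `genes.tsv` / `barcodes.tsv` with one identifier per line)
#' or a dense TSV/CSV whose header row holds the gene identifiers and
#' whose first column holds the cell identifiers.  The returned matrix
#' is always cells x genes.
#'
#' @param matrix_path path to the `.mtx` or dense table file.
#' @param genes_path,cells_path sidecar identifier files (required for
#'   MTX input; ignored for dense tables).
#' @return A [cell_matrix()] with `unit = "counts"`.
#' @export
read_expression_input <- function(matrix_path, genes_path = NULL,
                                  cells_path = NULL) {
  if (!file.exists(matrix_path)) stop("no such file: ", matrix_path)
  if (grepl("\\.mtx$", matrix_path, ignore.case = TRUE)) {
    if (is.null(genes_path) || is.null(cells_path))
      stop("MTX input needs genes_path and cells_path sidecars")
    m <- Matrix::readMM(matrix_path)          # genes x cells on disk
    genes <- read.delim(genes_path, header = FALSE,
                        stringsAsFactors = FALSE)[[1]]
    cells <- read.delim(cells_path, header = FALSE,
                        stringsAsFactors = FALSE)[[1]]
    if (length(genes) != nrow(m))
      stop("gene sidecar has ", length(genes), " ids but matrix declares ",
           nrow(m), " rows")
    if (length(cells) != ncol(m))
      stop("cell sidecar has ", length(cells), " ids but matrix declares ",
           ncol(m), " columns")
    cell_matrix(as(Matrix::t(m), "CsparseMatrix"), cells, genes,
                unit = "counts")
  } else {
    sep <- if (grepl("\\.csv$", matrix_path, ignore.case = TRUE)) "," else "\t"
    tab <- read.delim(matrix_path, sep = sep, header = TRUE,
                      check.names = FALSE, stringsAsFactors = FALSE)
    cells <- as.character(tab[[1]])
    vals <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    cell_matrix(vals, cells, colnames(tab)[-1], unit = "counts")
  }
}

#' Write an expression matrix as MTX plus sidecars
#'
#' Writes `matrix.mtx` (genes x cells, the on-disk convention),
#' `genes.tsv` and `barcodes.tsv` into a directory.
#'
#' @param counts a [cell_matrix()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_expression_mtx <- function(counts, dir) {
  stopifnot(is(counts, "cell_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::t(as(as(counts$values, "CsparseMatrix"), "generalMatrix"))
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(counts$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(counts$cell_ids, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Write a prediction table as TSV
#'
#' Header: `cell_id`, one probability column per class (6 decimal
#' places), `predicted_label`.
#'
#' @param table a prediction data frame from [predict.eigencell()] /
#'   [assign_labels()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(table, path) {
  stopifnot(is.data.frame(table))
  prob_cols <- setdiff(names(table),
                       c("cell_id", "predicted_label", "max_probability",
                         "depth"))
  out <- data.frame(cell_id = table$cell_id, check.names = FALSE)
  for (cn in prob_cols) out[[cn]] <- sprintf("%.6f", table[[cn]])
  out$predicted_label <- table$predicted_label
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a prediction TSV written by [write_predictions()]
#'
#' @param path the file.
#' @return Data frame with `cell_id`, numeric probability columns and
#'   `predicted_label`.
#' @export
read_predictions <- function(path) {
  tab <- read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (cn in setdiff(names(tab), c("cell_id", "predicted_label")))
    tab[[cn]] <- as.numeric(tab[[cn]])
  tab
}

bundle_format_version <- "1.0"

sha256_file <- function(path) digest::digest(file = path, algo = "sha256")

write_tsv <- function(df, path)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

safe_name <- function(x) gsub("[^A-Za-z0-9_.-]", "_", x)

#' Save a fitted model as a portable bundle directory
#'
#' Writes a directory of plain-text files — a JSON manifest plus one TSV
#' or JSON file per array (rotation, scaling, per-class PC selections
#' and SVM parameters) — that fully reconstructs the classifier without
#' the training data.  Every file is listed in the manifest with its
#' SHA-256 checksum, so silent corruption is detected on load.
#'
#' @param bundle a fitted [eigencell()] model.
#' @param dir output directory (created; must be empty or absent).
#' @return The manifest, invisibly.
#' @export
save_model_bundle <- function(bundle, dir) {
  stopifnot(is(bundle, "eigencell"))
  need <- if (bundle$collapse_binary) bundle$class_names[2] else
    bundle$class_names
  missing_models <- setdiff(need, names(bundle$models))
  if (length(missing_models))
    stop("partial bundle: no model for ",
         paste(missing_models, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- bundle$eigenspace
  files <- character(0)
  put <- function(name, writer) {
    writer(file.path(dir, name))
    files[[name]] <<- sha256_file(file.path(dir, name))
  }
  put("scaling.tsv", function(p) write_tsv(
    data.frame(gene_id = sp$scaling$gene_ids, mu = sp$scaling$mu,
               sigma = sp$scaling$sigma), p))
  put("rotation.tsv", function(p) write_tsv(
    data.frame(gene_id = sp$gene_ids, sp$rotation, check.names = FALSE), p))
  put("eigen.json", function(p) jsonlite::write_json(
    list(singular_values = sp$singular_values,
         var_explained = sp$var_explained,
         total_variance = sp$total_variance, n_cells = sp$n_cells),
    p, digits = NA, auto_unbox = TRUE))
  class_files <- list()
  for (cn in names(bundle$models)) {
    m <- bundle$models[[cn]]
    sel <- bundle$selections[[cn]]
    sn <- safe_name(cn)
    sel_f <- paste0("selection_", sn, ".tsv")
    svm_f <- paste0("svm_", sn, ".json")
    sv_f <- paste0("sv_", sn, ".tsv")
    put(sel_f, function(p) write_tsv(selection_table(sel), p))
    put(svm_f, function(p) jsonlite::write_json(
      list(class_name = cn, kernel_sigma = m$kernel_sigma, cost = m$cost,
           intercept = m$intercept, platt_a = m$platt_a,
           platt_b = m$platt_b, pc_indices = m$pc_indices,
           alpha = sel$alpha), p, digits = NA, auto_unbox = TRUE))
    put(sv_f, function(p) write_tsv(
      data.frame(dual_coef = m$dual_coefs, m$support_vectors,
                 check.names = FALSE), p))
    class_files[[cn]] <- list(selection = sel_f, svm = svm_f,
                              support_vectors = sv_f)
  }
  manifest <- list(format_version = bundle_format_version,
                   package = "eigencell",
                   package_version = as.character(packageVersion("eigencell")),
                   class_names = bundle$class_names,
                   collapse_binary = bundle$collapse_binary,
                   threshold = bundle$threshold,
                   parameters = bundle$parameters,
                   n_genes = length(sp$gene_ids),
                   class_files = class_files,
                   files = as.list(files))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Load a model bundle directory
#'
#' Verifies the manifest and every file checksum, then reconstructs a
#' predict-ready [eigencell()] model (training scores and labels are
#' not part of a bundle).
#'
#' @param dir a directory written by [save_model_bundle()].
#' @return An `eigencell` model.
#' @export
load_model_bundle <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp))
    stop("not a model bundle: no manifest.json in ", dir)
  manifest <- jsonlite::read_json(mp, simplifyVector = TRUE)
  if (is.null(manifest$format_version) ||
      numeric_version(manifest$format_version) >
      numeric_version(bundle_format_version))
    stop("bundle format version ", manifest$format_version,
         " is newer than supported (", bundle_format_version, ")")
  for (f in names(manifest$files)) {
    fp <- file.path(dir, f)
    if (!file.exists(fp)) stop("bundle file missing: ", f)
    if (!identical(sha256_file(fp), manifest$files[[f]]))
      stop("checksum mismatch for bundle file ", f)
  }
  scal <- read.delim(file.path(dir, "scaling.tsv"),
                     stringsAsFactors = FALSE)
  scaling <- structure(list(mu = scal$mu, sigma = scal$sigma,
                            gene_ids = as.character(scal$gene_id),
                            dropped_genes = character(0)),
                       class = "gene_scaling")
  rot <- read.delim(file.path(dir, "rotation.tsv"), check.names = FALSE,
                    stringsAsFactors = FALSE)
  rotation <- as.matrix(rot[, -1, drop = FALSE])
  rownames(rotation) <- as.character(rot$gene_id)
  ei <- jsonlite::read_json(file.path(dir, "eigen.json"),
                            simplifyVector = TRUE)
  space <- structure(list(rotation = rotation,
                          singular_values = ei$singular_values,
                          scores = NULL,
                          var_explained = ei$var_explained,
                          total_variance = ei$total_variance,
                          gene_ids = rownames(rotation),
                          cell_ids = NULL, n_cells = ei$n_cells,
                          scaling = scaling),
                     class = "eigenspace")
  models <- list()
  selections <- list()
  for (cn in names(manifest$class_files)) {
    cf <- manifest$class_files[[cn]]
    sj <- jsonlite::read_json(file.path(dir, cf$svm),
                              simplifyVector = TRUE)
    sv <- read.delim(file.path(dir, cf$support_vectors),
                     check.names = FALSE, stringsAsFactors = FALSE)
    seltab <- read.delim(file.path(dir, cf$selection),
                         stringsAsFactors = FALSE)
    chosen <- seltab[seltab$selected, , drop = FALSE]
    chosen <- chosen[order(chosen$p_adj, chosen$pc_index), , drop = FALSE]
    selections[[cn]] <- structure(
      list(class_name = cn, pc_indices = chosen$pc_index,
           p_raw = setNames(seltab$p_raw, seltab$pc_index),
           p_adj = setNames(seltab$p_adj, seltab$pc_index),
           alpha = sj$alpha),
      class = "pc_selection")
    models[[cn]] <- structure(
      list(support_vectors = as.matrix(sv[, -1, drop = FALSE]),
           dual_coefs = sv$dual_coef, intercept = sj$intercept,
           kernel_sigma = sj$kernel_sigma, cost = sj$cost,
           platt_a = sj$platt_a, platt_b = sj$platt_b,
           cv_summary = NULL, class_name = cn,
           pc_indices = sj$pc_indices),
      class = "svm_model")
  }
  structure(list(eigenspace = space, selections = selections,
                 models = models, class_names = manifest$class_names,
                 threshold = manifest$threshold, labels = NULL,
                 collapse_binary = isTRUE(manifest$collapse_binary),
                 parameters = manifest$parameters,
                 call = NULL),
            class = "eigencell")
}
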