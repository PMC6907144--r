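#' Simulate class-structured single-cell count matrices
#'
#' Generates negative-binomial counts with the statistical structure the
#' classifier assumes: per-gene baseline means drawn log-normally, each
#' class shifting a dedicated block of effect genes upward by
#' `effect_size` log2 units (many small effects spread across genes),
#' per-cell library sizes drawn uniformly from `library_size_range`,
#' and mitochondrial / ribosomal genes tagged by the conventional
#' `MT-` / `RPL`/`RPS` identifier prefixes.  Effect-gene blocks are
#' disjoint across classes, including the optional unseen class, so
#' recovery and rejection experiments have verifiable ground truth.
#'
#' @param n_cells_per_class cells per class (default 200).
#' @param n_genes total genes (default 1000).
#' @param n_classes number of training classes (default 2); ignored when
#'   `class_names` is given.
#' @param class_names optional class names (default `classA`,
#'   `classB`, ...).
#' @param n_effect_genes shifted genes per class (default 200).
#' @param effect_size log2 fold shift of the effect genes (default 1).
#' @param dispersion negative-binomial dispersion (`1/size`;
#'   default 0.5).
#' @param library_size_range per-cell library-size range
#'   (default 5000-20000).
#' @param n_mito,n_ribo numbers of tagged mitochondrial / ribosomal
#'   genes (never effect genes).
#' @param unseen_class also generate an `"unseen"` class with its own
#'   disjoint effect-gene block (for rejection experiments).
#' @param batch_shift optional list of per-batch log2-fold vectors
#'   (length `n_genes`); cells are assigned to batches round-robin.
#' @param seed RNG seed (mandatory; the output is a deterministic
#'   function of the configuration and the seed).
#' @return List with `counts` (a [cell_matrix()]), `labels` (named
#'   character vector) and `manifest` (ground truth: per-class effect
#'   genes, `effect_size`, per-gene baseline and class means, drawn
#'   library sizes, batch assignment).
#' @export
simulate_cells <- function(n_cells_per_class = 200, n_genes = 1000,
                           n_classes = 2, class_names = NULL,
                           n_effect_genes = 200, effect_size = 1,
                           dispersion = 0.5,
                           library_size_range = c(5000, 20000),
                           n_mito = 10, n_ribo = 20,
                           unseen_class = FALSE, batch_shift = NULL,
                           seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(class_names))
    class_names <- paste0("class", LETTERS[seq_len(n_classes)])
  all_classes <- c(class_names, if (unseen_class) "unseen")
  n_tagged <- n_mito + n_ribo
  if (n_effect_genes * length(all_classes) > n_genes - n_tagged)
    stop("effect-gene blocks exceed the number of untagged genes")
  gene_ids <- c(if (n_mito) paste0("MT-SIM", seq_len(n_mito)),
                if (n_ribo) paste0("RPL-SIM", seq_len(n_ribo)),
                paste0("GENE", seq_len(n_genes - n_tagged)))
  with_seed(seed, {
    base <- rlnorm(n_genes, meanlog = 1, sdlog = 1)
    pool <- which(seq_len(n_genes) > n_tagged)
    effect_genes <- list()
    offset <- 0
    for (cn in all_classes) {
      effect_genes[[cn]] <- pool[offset + seq_len(n_effect_genes)]
      offset <- offset + n_effect_genes
    }
    class_means <- sapply(all_classes, function(cn) {
      mu <- base
      mu[effect_genes[[cn]]] <- mu[effect_genes[[cn]]] * 2^effect_size
      mu
    })
    n_total <- n_cells_per_class * length(all_classes)
    labels <- rep(all_classes, each = n_cells_per_class)
    lib <- round(runif(n_total, library_size_range[1],
                       library_size_range[2]))
    batch <- if (is.null(batch_shift)) rep(1L, n_total) else
      rep_len(seq_along(batch_shift), n_total)
    counts <- matrix(0L, n_total, n_genes)
    for (i in seq_len(n_total)) {
      mu <- class_means[, labels[i]]
      if (!is.null(batch_shift))
        mu <- mu * 2^batch_shift[[batch[i]]]
      p <- mu / sum(mu)
      counts[i, ] <- rnbinom(n_genes, mu = lib[i] * p,
                             size = 1 / dispersion)
    }
    cell_ids <- sprintf("cell%04d", seq_len(n_total))
    names(labels) <- cell_ids
    manifest <- list(class_names = all_classes,
                     effect_genes = lapply(effect_genes,
                                           function(ix) gene_ids[ix]),
                     effect_size = effect_size,
                     base_means = setNames(base, gene_ids),
                     class_means = `dimnames<-`(class_means,
                                                list(gene_ids, all_classes)),
                     library_sizes = setNames(lib, cell_ids),
                     batch = setNames(batch, cell_ids),
                     dispersion = dispersion, seed = seed)
    list(counts = cell_matrix(counts, cell_ids, gene_ids, unit = "counts"),
         labels = labels, manifest = manifest)
  })
}

#' Simulate a hierarchical (lineage-tree) dataset
#'
#' Every internal node of the tree contributes a shared effect-gene
#' block to all of its descendant leaves, and every leaf adds its own
#' block, all blocks disjoint.  Sibling leaves therefore share their
#' ancestors' shifts and are more similar to each other than to
#' non-siblings.  Labels carry the full path (e.g.
#' `"lymphoid/T/cytotoxic"`).
#'
#' @param hierarchy nested named list describing the tree, e.g.
#'   `list(lymphoid = list(T = NULL, B = NULL), myeloid = NULL)`; `NULL`
#'   marks a leaf.
#' @param n_cells_per_class cells per leaf.
#' @param n_genes,n_effect_genes,effect_size,dispersion,
#'   library_size_range,n_mito,n_ribo,seed as in [simulate_cells()];
#'   `n_effect_genes` is the block size per tree node.
#' @return List with `counts`, path `labels` and a ground-truth
#'   `manifest` (per-node effect genes and per-leaf means).
#' @export
simulate_hierarchy <- function(hierarchy, n_cells_per_class = 100,
                               n_genes = 1000, n_effect_genes = 50,
                               effect_size = 1, dispersion = 0.5,
                               library_size_range = c(5000, 20000),
                               n_mito = 10, n_ribo = 20, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (!is.list(hierarchy) || is.null(names(hierarchy)))
    stop("hierarchy must be a named nested list")
  # flatten: one row per node with its path; leaves marked
  nodes <- list()
  walk <- function(tree, path) {
    for (nm in names(tree)) {
      p <- if (nzchar(path)) paste(path, nm, sep = "/") else nm
      leaf <- is.null(tree[[nm]]) || length(tree[[nm]]) == 0
      nodes[[p]] <<- leaf
      if (!leaf) walk(tree[[nm]], p)
    }
  }
  walk(hierarchy, "")
  paths <- names(nodes)
  leaves <- paths[unlist(nodes)]
  n_tagged <- n_mito + n_ribo
  if (length(paths) * n_effect_genes > n_genes - n_tagged)
    stop("effect-gene blocks exceed the number of untagged genes")
  gene_ids <- c(if (n_mito) paste0("MT-SIM", seq_len(n_mito)),
                if (n_ribo) paste0("RPL-SIM", seq_len(n_ribo)),
                paste0("GENE", seq_len(n_genes - n_tagged)))
  with_seed(seed, {
    base <- rlnorm(n_genes, meanlog = 1, sdlog = 1)
    pool <- which(seq_len(n_genes) > n_tagged)
    effect_genes <- list()
    for (i in seq_along(paths))
      effect_genes[[paths[i]]] <- pool[(i - 1) * n_effect_genes +
                                         seq_len(n_effect_genes)]
    leaf_means <- sapply(leaves, function(lf) {
      mu <- base
      anc <- Reduce(function(a, b) paste(a, b, sep = "/"),
                    strsplit(lf, "/", fixed = TRUE)[[1]], accumulate = TRUE)
      for (p in anc)
        mu[effect_genes[[p]]] <- mu[effect_genes[[p]]] * 2^effect_size
      mu
    })
    n_total <- n_cells_per_class * length(leaves)
    labels <- rep(leaves, each = n_cells_per_class)
    lib <- round(runif(n_total, library_size_range[1],
                       library_size_range[2]))
    counts <- matrix(0L, n_total, n_genes)
    for (i in seq_len(n_total)) {
      p <- leaf_means[, labels[i]] / sum(leaf_means[, labels[i]])
      counts[i, ] <- rnbinom(n_genes, mu = lib[i] * p,
                             size = 1 / dispersion)
    }
    cell_ids <- sprintf("cell%04d", seq_len(n_total))
    names(labels) <- cell_ids
    manifest <- list(paths = paths, leaves = leaves,
                     effect_genes = lapply(effect_genes,
                                           function(ix) gene_ids[ix]),
                     effect_size = effect_size,
                     leaf_means = `dimnames<-`(leaf_means,
                                               list(gene_ids, leaves)),
                     library_sizes = setNames(lib, cell_ids), seed = seed)
    list(counts = cell_matrix(counts, cell_ids, gene_ids, unit = "counts"),
         labels = labels, manifest = manifest)
  })
}
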