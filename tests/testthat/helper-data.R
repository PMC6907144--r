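# shared fixture builders; all data is generated in code

# tiny deterministic counts matrix with controllable library sizes:
# gene1 carries libsize - rest, gene2..k split the remainder
toy_counts <- function(libsizes, n_genes = 3, gene_ids = NULL,
                       cell_ids = NULL) {
  n <- length(libsizes)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(n_genes))
  if (is.null(cell_ids)) cell_ids <- paste0("c", seq_len(n))
  v <- matrix(0, n, n_genes)
  base <- pmin(libsizes %/% 2, 10)
  v[, 1] <- libsizes - base
  if (n_genes > 1) v[, 2] <- base
  cell_matrix(v, cell_ids, gene_ids, unit = "counts")
}

# small class-structured simulation shared by several unit tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_cells(n_cells_per_class = 60, n_genes = 300,
                               n_effect_genes = 60, effect_size = 1.5,
                               seed = 101)
    cache
  }
})

# a fitted small model shared by predictor / io tests
small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- small_sim()
      cache <<- eigencell(sim$counts, sim$labels, folds = 4,
                          grid = list(sigma = c(0.05, 0.2),
                                      cost = c(1, 4)),
                          seed = 7)
    }
    cache
  }
})

# fake eigenspace with prescribed variance profile, for filter tests
fake_eigenspace <- function(var_explained, n_cells = 10) {
  k <- length(var_explained)
  structure(list(rotation = diag(k), singular_values = sqrt(var_explained),
                 scores = matrix(rnorm(n_cells * k), n_cells, k),
                 var_explained = var_explained, total_variance = 1,
                 gene_ids = paste0("g", seq_len(k)),
                 cell_ids = paste0("c", seq_len(n_cells)),
                 n_cells = n_cells, scaling = NULL),
            class = "eigenspace")
}

# wrap a plain matrix as a scaled_matrix (bypasses centring, for
# linear-algebra tests on prescribed inputs)
as_scaled <- function(m, gene_ids = colnames(m), cell_ids = rownames(m)) {
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(m)))
  if (is.null(cell_ids)) cell_ids <- paste0("c", seq_len(nrow(m)))
  dimnames(m) <- list(cell_ids, gene_ids)
  structure(list(values = m, cell_ids = cell_ids, gene_ids = gene_ids,
                 scaling = NULL),
            class = "scaled_matrix")
}
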