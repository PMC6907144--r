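#' Hierarchical classifier node
#'
#' A node of a lineage-tree classifier (e.g. myeloid / lymphoid /
#' progenitor at the root, then B / T / NK under lymphoid, then
#' cytotoxic status under T).  Each node holds a fitted [eigencell()]
#' bundle; a child is consulted only for cells the parent assigned to
#' that child's class.
#'
#' @param name node name (the root is conventionally `"root"`).
#' @param bundle a fitted [eigencell()] model.
#' @param children named list of `hierarchy_node` objects; names must be
#'   a subset of `bundle$class_names`.
#' @return A `hierarchy_node` object.
#' @export
hierarchy_node <- function(name, bundle, children = list()) {
  stopifnot(is(bundle, "eigencell"))
  if (length(children)) {
    if (is.null(names(children)) || any(names(children) == ""))
      stop("children must be a named list")
    bad <- setdiff(names(children), bundle$class_names)
    if (length(bad))
      stop("child keys not among the node's classes: ",
           paste(bad, collapse = ", "))
    ok <- vapply(children, function(ch) is(ch, "hierarchy_node"), TRUE)
    if (!all(ok)) stop("children must be hierarchy_node objects")
  }
  structure(list(name = name, bundle = bundle, children = children),
            class = "hierarchy_node")
}

#' @export
print.hierarchy_node <- function(x, indent = 0, ...) {
  cat(strrep("  ", indent), "<hierarchy_node> ", x$name, ": ",
      paste(x$bundle$class_names, collapse = ", "), "\n", sep = "")
  for (nm in names(x$children)) print(x$children[[nm]], indent + 1)
  invisible(x)
}

#' Hierarchical prediction
#'
#' Classifies cells down a lineage tree.  Every cell is scored by the
#' root bundle; cells assigned a class that has a child node are passed
#' to that child, and so on.  The final label is the deepest successful
#' assignment path joined by `/` (e.g. `"lymphoid/T/cytotoxic"`).  A
#' cell rejected at some level keeps the path assigned so far; a cell
#' rejected at the root is `"Unassigned"`.
#'
#' @param root a [hierarchy_node()].
#' @param test_counts a raw-count [cell_matrix()].
#' @param threshold rejection threshold applied at every level.
#' @return Data frame with `cell_id`, `predicted_label` (full path),
#'   `depth` (number of assigned levels) and `max_probability` at the
#'   last successful level (root-level value for unassigned cells).
#' @export
predict_hierarchical <- function(root, test_counts, threshold = 0.9) {
  stopifnot(is(root, "hierarchy_node"), is(test_counts, "cell_matrix"))
  n <- length(test_counts$cell_ids)
  res <- data.frame(cell_id = test_counts$cell_ids,
                    predicted_label = rep("Unassigned", n),
                    depth = rep(0L, n),
                    max_probability = rep(NA_real_, n))
  walk <- function(node, idx, path, depth) {
    sub <- cm_subset(test_counts, cells = idx)
    pred <- predict(node$bundle, sub, threshold = threshold)
    if (depth == 1L) res$max_probability[idx] <<- pred$max_probability
    assigned <- pred$predicted_label != "Unassigned"
    if (any(assigned)) {
      ai <- idx[assigned]
      res$predicted_label[ai] <<- if (nzchar(path))
        paste(path, pred$predicted_label[assigned], sep = "/")
      else pred$predicted_label[assigned]
      res$depth[ai] <<- depth
      res$max_probability[ai] <<- pred$max_probability[assigned]
      for (cn in names(node$children)) {
        ci <- idx[assigned & pred$predicted_label == cn]
        if (length(ci))
          walk(node$children[[cn]], ci,
               if (nzchar(path)) paste(path, cn, sep = "/") else cn,
               depth + 1L)
      }
    }
  }
  if (n > 0) walk(root, seq_len(n), "", 1L)
  res
}

#' Train a hierarchy of classifiers from path labels
#'
#' Builds a lineage tree from labels of the form
#' `"lymphoid/T/cytotoxic"`: the root model is trained on the first path
#' component of every cell, and a child model is trained for each class
#' whose cells carry deeper path components.
#'
#' @param counts a raw-count [cell_matrix()].
#' @param path_labels per-cell labels; levels separated by `sep`.
#' @param sep path separator (default `"/"`).
#' @param node_name name for the root node.
#' @param ... passed to [eigencell()] at every node.
#' @return A [hierarchy_node()] tree.
#' @export
eigencell_hierarchy <- function(counts, path_labels, sep = "/",
                                node_name = "root", ...) {
  stopifnot(is(counts, "cell_matrix"))
  path_labels <- as.character(path_labels)
  parts <- strsplit(path_labels, sep, fixed = TRUE)
  top <- vapply(parts, `[[`, "", 1L)
  rest <- vapply(parts, function(p)
    if (length(p) > 1) paste(p[-1], collapse = sep) else NA_character_, "")
  bundle <- eigencell(counts, top, ...)
  kept <- counts$cell_ids %in% names(bundle$labels)
  children <- list()
  for (cn in unique(top)) {
    sel <- kept & top == cn & !is.na(rest)
    if (sum(sel) > 0 && length(unique(rest[sel])) > 1) {
      sub <- cm_subset(counts, cells = which(sel))
      children[[cn]] <- eigencell_hierarchy(sub, rest[sel], sep = sep,
                                            node_name = cn, ...)
    }
  }
  hierarchy_node(node_name, bundle, children)
}
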