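# Rooted binary gene trees (MUL-trees: leaf labels may repeat).

new_gene_tree <- function(children, label, root) {
  n <- length(children)
  parent <- rep(NA_integer_, n)
  for (v in seq_len(n)) {
    for (w in children[[v]]) {
      if (!is.na(parent[w])) stop_input("node %d has two parents in a tree", w)
      parent[w] <- v
    }
  }
  is_leaf <- lengths(children) == 0L
  if (!any(is_leaf)) stop_input("tree has no leaves")
  if (any(is_leaf & is.na(label))) stop_input("unlabeled leaf in gene tree")
  structure(list(
    n = n,
    children = children,
    label = label,
    root = root,
    parent = parent,
    is_leaf = is_leaf,
    postorder = post_order(children, root)
  ), class = "gene_tree")
}

#' Parse a rooted binary gene tree from a Newick string
#'
#' Gene trees are MUL-trees: repeated leaf labels are legal. Branch lengths
#' and internal labels are accepted on input and ignored; hybrid (`#H`) tags
#' are rejected. Every internal node must have exactly two children.
#'
#' @param text a Newick string (semicolon-terminated), or a character vector
#'   of lines that concatenate to one.
#' @return an object of class `gene_tree`.
#' @examples
#' g <- parse_gene_tree("((a,(b,c)),d);")
#' n_edges(g)
#' @export
parse_gene_tree <- function(text) {
  raw <- parse_newick_raw(text)
  if (any(!is.na(raw$tag)))
    stop_input("hybrid '#H' tags are not allowed in a gene tree")
  outd <- lengths(raw$children)
  if (any(outd != 0L & outd != 2L)) stop_input("non-binary gene tree")
  label <- raw$label
  label[outd > 0L] <- NA_character_ # internal labels ignored for topology
  new_gene_tree(raw$children, label, raw$root)
}

#' Number of edges of a gene tree
#' @param g a `gene_tree`
#' @return integer, `|E(G)|`
#' @export
n_edges <- function(g) g$n - 1L

#' Leaf labels of a gene tree (with multiplicity, in node-id order)
#' @param g a `gene_tree`
#' @return character vector
#' @export
leaf_labels <- function(g) g$label[g$is_leaf]

# Subtree leaf counts and the uniform leaf label (NA when mixed) per node;
# used by the DP leaf cases.
gt_leaf_summary <- function(g) {
  n <- g$n
  nleaf <- integer(n)
  ulab <- character(n)
  for (v in g$postorder) {
    if (g$is_leaf[v]) {
      nleaf[v] <- 1L
      ulab[v] <- g$label[v]
    } else {
      ch <- g$children[[v]]
      nleaf[v] <- sum(nleaf[ch])
      u <- unique(ulab[ch])
      ulab[v] <- if (length(u) == 1L && !anyNA(u)) u else NA_character_
    }
  }
  list(nleaf = nleaf, ulab = ulab)
}

# Labels present below each node, as a list of character sets.
gt_label_sets <- function(g) {
  sets <- vector("list", g$n)
  for (v in g$postorder) {
    sets[[v]] <- if (g$is_leaf[v]) g$label[v]
      else unique(unlist(sets[g$children[[v]]], use.names = FALSE))
  }
  sets
}

gt_depths <- function(g) {
  d <- integer(g$n)
  for (v in rev(g$postorder)) {
    if (!is.na(g$parent[v])) d[v] <- d[g$parent[v]] + 1L
  }
  d
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("gene tree:", sum(x$is_leaf), "leaves,", n_edges(x), "edges\n")
  cat(" ", serialize_newick(x), "\n")
  invisible(x)
}
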