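# Classic tree-tree reconciliation: lca-mapping, deep coalescence cost,
# duplication cost, and the rooted variant used by the level-k solver.

as_species_tree <- function(S) {
  if (inherits(S, "phylo_network")) {
    if (n_reticulations(S) > 0L)
      stop_input("species tree expected, got a network with reticulations")
    S <- rw_to_tree(rw_fixpoint(rw_state(S)))
  }
  if (!inherits(S, "gene_tree")) stop_input("not a tree")
  if (anyDuplicated(leaf_labels(S)))
    stop_input("species tree labels must be one-to-one")
  S
}

#' Least-common-ancestor mapping of a gene tree into a species tree
#'
#' Maps every leaf of `G` to the same-labeled leaf of `S` and every internal
#' node to the lca of its children's images.
#'
#' @param G a `gene_tree` (MUL-trees allowed)
#' @param S a species tree (`gene_tree`/`displayed_tree` with one-to-one
#'   labels, or a reticulation-free `phylo_network`)
#' @return list of class `odt_lca_mapping`: `map` (int vector over V(G)),
#'   `depth` (depths in S), and the trees.
#' @export
lca_mapping <- function(G, S) {
  S <- as_species_tree(S)
  sdep <- gt_depths(S)
  sleaf <- which(S$is_leaf)
  leaf_of <- stats::setNames(sleaf, S$label[sleaf])
  map <- integer(G$n)
  lca2 <- function(a, b) {
    while (a != b) {
      if (sdep[a] >= sdep[b]) a <- S$parent[a] else b <- S$parent[b]
    }
    a
  }
  for (g in G$postorder) {
    if (G$is_leaf[g]) {
      m <- leaf_of[G$label[g]]
      if (is.na(m)) stop_input("unmappable leaf '%s'", G$label[g])
      map[g] <- m
    } else {
      ch <- G$children[[g]]
      map[g] <- lca2(map[ch[1]], map[ch[2]])
    }
  }
  structure(list(map = map, depth = sdep, G = G, S = S),
            class = "odt_lca_mapping")
}

#' Deep coalescence cost between a gene tree and a species tree
#'
#' Sum over gene-tree edges of (path length between the endpoint images
#' under the lca-mapping, minus one): the number of extra gene lineages of
#' the embedding.
#'
#' @inheritParams lca_mapping
#' @return nonnegative integer
#' @export
dc_cost <- function(G, S) {
  m <- lca_mapping(G, S)
  total <- 0L
  for (v in seq_len(G$n)) {
    for (w in G$children[[v]]) {
      total <- total + (m$depth[m$map[w]] - m$depth[m$map[v]]) - 1L
    }
  }
  as.integer(total)
}

#' Duplication cost between a gene tree and a species tree
#'
#' Counts internal gene nodes that map to the same species node as one of
#' their children.
#'
#' @inheritParams lca_mapping
#' @return nonnegative integer, at most the number of internal nodes of `G`
#' @export
dup_cost <- function(G, S) {
  m <- lca_mapping(G, S)
  total <- 0L
  for (g in which(!G$is_leaf)) {
    ch <- G$children[[g]]
    if (m$map[g] == m$map[ch[1]] || m$map[g] == m$map[ch[2]])
      total <- total + 1L
  }
  total
}

#' Rooted deep coalescence cost (the per-tree DC-up summand)
#'
#' `dc_cost(G, S)` plus the number of edges between the species root and the
#' image of the gene root: the objective charged to a non-root blob by the
#' level-k solver.
#'
#' @inheritParams lca_mapping
#' @return nonnegative integer
#' @export
dc_up_cost <- function(G, S) {
  m <- lca_mapping(G, S)
  dc_cost(G, S) + as.integer(m$depth[m$map[G$root]])
}
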