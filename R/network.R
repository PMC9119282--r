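# Rooted binary phylogenetic networks as DAGs with reticulation nodes.
#
# Node ids are stable integers assigned in input order; surgery (edge removal,
# contraction) marks nodes dead rather than renumbering, so node ids and edge
# ids survive pruning. Every edge carries a persistent integer edge id (eid);
# contraction splices keep the eid of the bottom edge, so a reticulation edge
# of a pruned network always carries the eid it had in the original network.

new_phylo_network <- function(children, label, root, eid = NULL, alive = NULL,
                              times = NULL) {
  n <- length(children)
  alive <- alive %||% rep(TRUE, n)
  if (is.null(eid)) {
    eid <- vector("list", n)
    k <- 0L
    for (v in seq_len(n)) {
      m <- length(children[[v]])
      eid[[v]] <- if (m) seq.int(k + 1L, k + m) else integer(0)
      k <- k + m
    }
  }
  parents <- vector("list", n)
  in_eid <- vector("list", n)
  for (v in which(alive)) {
    ch <- children[[v]]
    for (i in seq_along(ch)) {
      w <- ch[i]
      parents[[w]] <- c(parents[[w]], v)
      in_eid[[w]] <- c(in_eid[[w]], eid[[v]][i])
    }
  }
  indeg <- lengths(parents)
  outdeg <- lengths(children)
  indeg[!alive] <- 0L
  outdeg[!alive] <- 0L
  kind <- rep(NA_character_, n)
  kind[alive] <- "tree"
  kind[alive & outdeg == 0L] <- "leaf"
  kind[alive & indeg >= 2L] <- "reticulation"
  kind[root] <- "root"
  topo <- topo_order(children, alive)
  if (topo[1] != root || any(indeg[alive & seq_len(n) != root] == 0L))
    stop_input("network is not rooted at a single node")
  retic <- which(alive & kind == "reticulation")
  re <- if (length(retic)) {
    do.call(rbind, lapply(sort(retic), function(r) {
      ord <- order(parents[[r]], in_eid[[r]])
      data.frame(tail = parents[[r]][ord], head = r, eid = in_eid[[r]][ord])
    }))
  } else {
    data.frame(tail = integer(0), head = integer(0), eid = integer(0))
  }
  structure(list(
    n = n, children = children, label = label, root = root,
    eid = eid, alive = alive, parents = parents, in_eid = in_eid,
    indeg = indeg, outdeg = outdeg, kind = kind, topo = topo,
    retic = sort(retic), retic_edges = re, times = times
  ), class = "phylo_network")
}

#' Parse a phylogenetic network from an extended-Newick string
#'
#' Hybrid nodes are written with `#H<int>` tags; every distinct tag denotes
#' one reticulation node with exactly two parents. The hybrid node's child
#' subtree may be attached at any single occurrence of the tag (`(b)#H1`),
#' and both `label#H1` and bare `#H1` forms are accepted. Branch lengths are
#' ignored. Leaf labels must be one-to-one.
#'
#' @param text an extended-Newick string.
#' @return an object of class `phylo_network`.
#' @examples
#' net <- parse_enewick("((a,(b)#H1)u,(#H1,c)v)r;")
#' n_reticulations(net)
#' @export
parse_enewick <- function(text) {
  raw <- parse_newick_raw(text)
  n <- length(raw$label)
  children <- raw$children
  label <- raw$label
  parent_of <- rep(NA_integer_, n)
  for (v in seq_len(n)) for (w in children[[v]]) parent_of[w] <- v

  tags <- unique(raw$tag[!is.na(raw$tag)])
  keep <- rep(TRUE, n)
  for (tg in tags) {
    occ <- which(raw$tag == tg)
    with_kids <- occ[lengths(children[occ]) > 0L]
    if (length(with_kids) > 1L)
      stop_input("hybrid tag #%s carries more than one child subtree", tg)
    if (length(with_kids) == 0L)
      stop_input("hybrid tag #%s carries no child subtree", tg)
    main <- with_kids
    refs <- setdiff(occ, main)
    if (length(occ) != 2L)
      stop_input("hybrid tag #%s must have exactly 2 parents (found %d)",
                 tg, length(occ))
    for (rf in refs) {
      p <- parent_of[rf]
      if (is.na(p)) stop_input("hybrid tag #%s occurs at the root", tg)
      children[[p]][children[[p]] == rf] <- main
      keep[rf] <- FALSE
    }
  }

  # compact ids (drop merged reference occurrences)
  newid <- cumsum(keep)
  newid[!keep] <- NA_integer_
  ch2 <- lapply(which(keep), function(v) newid[children[[v]]])
  lab2 <- label[keep]
  outd <- lengths(ch2)
  lab2[outd > 0L] <- NA_character_ # internal labels ignored
  leaf_lab <- lab2[outd == 0L]
  if (anyNA(leaf_lab)) stop_input("unlabeled leaf in network")
  if (anyDuplicated(leaf_lab))
    stop_input("duplicate leaf label '%s' in network",
               leaf_lab[duplicated(leaf_lab)][1])
  new_phylo_network(ch2, lab2, newid[raw$root])
}

#' Number of (live) nodes of a network
#' @param net a `phylo_network`
#' @export
n_nodes <- function(net) sum(net$alive)

#' Number of reticulation nodes of a network
#' @param net a `phylo_network`
#' @export
n_reticulations <- function(net) length(net$retic)

#' Reticulation edges of a network
#'
#' @param net a `phylo_network`
#' @return a data.frame with columns `tail`, `head` (node ids; `head` is a
#'   reticulation) and `eid` (the persistent edge id), ordered by head then
#'   tail.
#' @export
retic_edges <- function(net) net$retic_edges

#' Species labels of a network
#' @param net a `phylo_network`
#' @return character vector of leaf labels (one-to-one).
#' @export
net_labels <- function(net) sort(net$label[net$alive & net$outdeg == 0L])

# All live edges as a data.frame(tail, head, eid).
net_edges <- function(net) {
  rows <- lapply(which(net$alive), function(v) {
    if (!length(net$children[[v]])) return(NULL)
    data.frame(tail = v, head = net$children[[v]], eid = net$eid[[v]])
  })
  out <- do.call(rbind, rows)
  out %||% data.frame(tail = integer(0), head = integer(0), eid = integer(0))
}

# eid -> (tail, head) lookup for a network.
eid_lookup <- function(net) {
  e <- net_edges(net)
  e[order(e$eid), , drop = FALSE]
}

#' Classify a phylogenetic network
#'
#' Computes the structural report used throughout: binarity of the DAG,
#' one-to-one leaf labeling, the tree-child property (every non-leaf node has
#' a non-reticulation child), the relaxed property (every node has at most
#' one reticulation child edge), the reticulation count r, and the level
#' (maximum number of reticulations in a biconnected component).
#'
#' @param net a `phylo_network`
#' @return a list of class `odt_class_report` with logical flags
#'   `is_binary`, `is_acyclic`, `labels_one_to_one`, `is_tree_child`,
#'   `is_relaxed`, and integers `r` and `level`.
#' @export
validate_network <- function(net) {
  live <- which(net$alive)
  k <- net$kind
  ind <- net$indeg
  outd <- net$outdeg
  ok_bin <- all(vapply(live, function(v) {
    switch(k[v],
      root = ind[v] == 0L && outd[v] == 2L,
      leaf = ind[v] == 1L && outd[v] == 0L,
      reticulation = ind[v] == 2L && outd[v] == 1L,
      tree = ind[v] == 1L && outd[v] == 2L,
      FALSE)
  }, logical(1)))
  leaves <- live[outd[live] == 0L]
  one2one <- !anyNA(net$label[leaves]) && !anyDuplicated(net$label[leaves])
  is_ret <- k == "reticulation"
  tree_child <- all(vapply(live[outd[live] > 0L], function(v) {
    any(!is_ret[net$children[[v]]])
  }, logical(1)))
  relaxed <- all(vapply(live, function(v) {
    sum(is_ret[net$children[[v]]]) <= 1L
  }, logical(1)))
  blobs <- decompose_blobs(net)
  structure(list(
    is_binary = ok_bin,
    is_acyclic = TRUE, # construction enforces acyclicity
    labels_one_to_one = one2one,
    is_tree_child = tree_child,
    is_relaxed = relaxed,
    r = n_reticulations(net),
    level = blobs$level
  ), class = "odt_class_report")
}

#' @export
print.odt_class_report <- function(x, ...) {
  cat(sprintf(
    "network class report: binary=%s, labels 1-1=%s, tree-child=%s, relaxed=%s, r=%d, level=%d\n",
    x$is_binary, x$labels_one_to_one, x$is_tree_child, x$is_relaxed,
    x$r, x$level))
  invisible(x)
}

#' Biconnected-component (blob) decomposition of a network
#'
#' Nontrivial biconnected components of the underlying undirected graph
#' (components with more than one edge), each annotated with its root (the
#' unique component node with no ancestor in the component) and its
#' reticulation count. Cut edges are not blobs. The quotient obtained by
#' contracting each blob is returned as an edge list between super-nodes.
#'
#' @param net a `phylo_network`
#' @return a list of class `odt_blobs`: `blobs` (list with `nodes`, `edges`,
#'   `root`, `n_retic`), `edge2blob` (named vector: eid -> blob index),
#'   `level`, `bc_edges` (quotient-tree edge list), and `bottom_up` (blob
#'   indices ordered deepest blob root first).
#' @export
decompose_blobs <- function(net) {
  e <- net_edges(net)
  empty <- list(blobs = list(),
                edge2blob = integer(0),
                level = 0L,
                bc_edges = data.frame(from = character(0), to = character(0)),
                bottom_up = integer(0))
  if (!nrow(e)) return(structure(empty, class = "odt_blobs"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e$tail), to = as.character(e$head)),
    directed = FALSE)
  bc <- igraph::biconnected_components(g)
  depth <- node_depths(net)
  blobs <- list()
  edge2blob <- rep(NA_integer_, max(e$eid))
  for (i in seq_along(bc$component_edges)) {
    eidx <- as.integer(bc$component_edges[[i]])
    if (length(eidx) < 2L) next # trivial component: a cut edge
    ends <- igraph::ends(g, eidx)
    comp_edges <- data.frame(
      tail = as.integer(ends[, 1]), head = as.integer(ends[, 2]))
    # restore orientation (graph_from_data_frame kept tail->head order)
    nodes <- sort(unique(c(comp_edges$tail, comp_edges$head)))
    root_b <- nodes[which.min(depth[nodes])]
    nret <- sum(net$kind[nodes] == "reticulation")
    bi <- length(blobs) + 1L
    blobs[[bi]] <- list(nodes = nodes, edges = comp_edges,
                        root = root_b, n_retic = nret)
    for (j in seq_len(nrow(comp_edges))) {
      m <- e$eid[e$tail == comp_edges$tail[j] & e$head == comp_edges$head[j]]
      edge2blob[m] <- bi
    }
  }
  lv <- if (length(blobs)) max(vapply(blobs, `[[`, integer(1), "n_retic"))
        else 0L
  # quotient tree: map nodes to super-ids (blob index or own id), merge blobs
  # that share nodes (chained contraction)
  super <- paste0("n", seq_len(net$n))
  for (i in seq_along(blobs)) super[blobs[[i]]$nodes] <- paste0("B", i)
  bc_edges <- unique(data.frame(from = super[e$tail], to = super[e$head]))
  bc_edges <- bc_edges[bc_edges$from != bc_edges$to, , drop = FALSE]
  rootd <- vapply(blobs, function(b) depth[b$root], numeric(1))
  structure(list(blobs = blobs, edge2blob = edge2blob, level = lv,
                 bc_edges = bc_edges,
                 bottom_up = order(rootd, decreasing = TRUE)),
            class = "odt_blobs")
}

# Depth of each live node (shortest directed distance from the root).
node_depths <- function(net) {
  d <- rep(NA_real_, net$n)
  d[net$root] <- 0
  for (v in net$topo) {
    for (w in net$children[[v]]) {
      d[w] <- min(d[w], d[v] + 1, na.rm = TRUE)
    }
  }
  d
}

#' @export
print.phylo_network <- function(x, ...) {
  cat(sprintf("phylogenetic network: %d nodes, %d leaves, r=%d\n",
              n_nodes(x), length(net_labels(x)), n_reticulations(x)))
  cat(" ", serialize_newick(x), "\n")
  invisible(x)
}
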