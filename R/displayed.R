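# Perfect sets (switchings), displayed-tree construction by edge deletion and
# contraction, and single-edge pruning N_e.
#
# Contraction is a small rewriting system applied to a fixed point:
#  (a) delete unlabeled outdegree-0 nodes together with their incoming edges,
#  (b) splice indegree-1/outdegree-1 (semi-binary) nodes,
#  (c) drop a unary root, promoting its child.
# The system is confluent; tests assert this under randomized scan orders.

rw_state <- function(net) {
  list(children = net$children, eid = net$eid, label = net$label,
       root = net$root, alive = net$alive, n = net$n)
}

rw_remove_eids <- function(st, eids) {
  if (!length(eids)) return(st)
  for (v in which(st$alive)) {
    keep <- !(st$eid[[v]] %in% eids)
    if (!all(keep)) {
      st$children[[v]] <- st$children[[v]][keep]
      st$eid[[v]] <- st$eid[[v]][keep]
    }
  }
  st
}

rw_fixpoint <- function(st, scan_seed = NULL) {
  repeat {
    indeg <- integer(st$n)
    for (v in which(st$alive)) for (w in st$children[[v]])
      indeg[w] <- indeg[w] + 1L
    live <- which(st$alive)
    if (!is.null(scan_seed)) {
      live <- live[sample.int(length(live))]
    }
    changed <- FALSE
    for (v in live) {
      if (!st$alive[v]) next
      outd <- length(st$children[[v]])
      if (outd == 0L && is.na(st$label[v])) {
        # rule (a): unlabeled leaf, drop with incoming edges
        st$alive[v] <- FALSE
        for (p in which(st$alive)) {
          keep <- st$children[[p]] != v
          st$children[[p]] <- st$children[[p]][keep]
          st$eid[[p]] <- st$eid[[p]][keep]
        }
        changed <- TRUE
      } else if (outd == 1L && v == st$root && indeg[v] == 0L) {
        # rule (c): unary root
        st$root <- st$children[[v]]
        st$children[[v]] <- integer(0)
        st$eid[[v]] <- integer(0)
        st$alive[v] <- FALSE
        changed <- TRUE
      } else if (outd == 1L && indeg[v] == 1L && v != st$root) {
        # rule (b): splice a semi-binary node; the bottom edge's eid survives
        child <- st$children[[v]]
        ceid <- st$eid[[v]]
        for (p in which(st$alive)) {
          i <- which(st$children[[p]] == v)
          if (length(i)) {
            st$children[[p]][i[1]] <- child
            st$eid[[p]][i[1]] <- ceid
          }
        }
        st$children[[v]] <- integer(0)
        st$eid[[v]] <- integer(0)
        st$alive[v] <- FALSE
        changed <- TRUE
      }
      if (changed) break
    }
    if (!changed) return(st)
  }
}

rw_to_network <- function(st, times = NULL) {
  new_phylo_network(st$children, st$label, st$root, eid = st$eid,
                    alive = st$alive, times = times)
}

# Convert a reticulation-free rewrite result into a gene_tree-shaped species
# tree (fresh compact ids), remembering the originating node ids.
rw_to_tree <- function(st) {
  live <- which(st$alive)
  newid <- rep(NA_integer_, st$n)
  newid[live] <- seq_along(live)
  children <- lapply(live, function(v) newid[st$children[[v]]])
  tr <- new_gene_tree(children, st$label[live], newid[st$root])
  attr(tr, "orig_id") <- live
  tr
}

# --- edge helpers -----------------------------------------------------------

as_edge_pair <- function(e) {
  if (is.data.frame(e)) return(c(e$tail[1], e$head[1]))
  if (length(e) == 2L) return(as.integer(e))
  stop_input("an edge must be given as c(tail, head) or a one-row data.frame")
}

find_retic_eid <- function(net, e) {
  p <- as_edge_pair(e)
  re <- net$retic_edges
  hit <- which(re$tail == p[1] & re$head == p[2])
  if (!length(hit))
    stop_input("<%d,%d> is not a reticulation edge of the network", p[1], p[2])
  re$eid[hit[1]]
}

#' Sibling of a reticulation edge
#'
#' Two reticulation edges are siblings when they share their head (bottom)
#' reticulation node; each reticulation edge of a binary network has exactly
#' one sibling.
#'
#' @param net a `phylo_network`
#' @param e an edge, as `c(tail, head)` node ids or a one-row data.frame.
#' @return a one-row data.frame(tail, head, eid).
#' @export
sibling_edge <- function(net, e) {
  eid <- find_retic_eid(net, e)
  re <- net$retic_edges
  h <- re$head[re$eid == eid]
  sib <- re[re$head == h & re$eid != eid, , drop = FALSE]
  rownames(sib) <- NULL
  sib
}

#' Enumerate all perfect sets (switchings) of a network
#'
#' A set of reticulation edges is perfect when it contains exactly one
#' incoming edge per reticulation. All `2^r` choices are produced in
#' deterministic order: reticulations by node id, first parent (lower tail
#' id) first.
#'
#' @param net a `phylo_network`
#' @param cap maximum reticulation count (guards the 2^r blow-up).
#' @return a list of data.frames (tail, head, eid), each of class
#'   `odt_perfect_set`.
#' @export
perfect_sets <- function(net, cap = 16L) {
  r <- n_reticulations(net)
  if (r > cap) stop_cap("2^%d perfect sets exceed the cap (r <= %d)", r, cap)
  re <- net$retic_edges
  per <- split(re, re$head)
  per <- per[order(as.integer(names(per)))]
  idx <- rep(1L, length(per))
  out <- vector("list", 2^r)
  for (i in seq_len(2^r)) {
    pick <- do.call(rbind, lapply(seq_along(per), function(j) {
      per[[j]][idx[j], , drop = FALSE]
    })) %||% re[0, , drop = FALSE]
    rownames(pick) <- NULL
    out[[i]] <- structure(pick, class = c("odt_perfect_set", "data.frame"))
    # odometer, first reticulation fastest
    j <- 1L
    while (j <= length(per)) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= nrow(per[[j]])) break
      idx[j] <- 1L
      j <- j + 1L
    }
  }
  out
}

check_perfect <- function(net, Y) {
  re <- net$retic_edges
  eids <- if (is.data.frame(Y)) Y$eid else as.integer(Y)
  if (!all(eids %in% re$eid)) stop_input("Y contains a non-reticulation edge")
  heads <- re$head[match(eids, re$eid)]
  if (anyDuplicated(heads) || !setequal(heads, net$retic))
    stop_input("Y is not a perfect set (one incoming edge per reticulation)")
  eids
}

#' Displayed tree induced by a perfect set
#'
#' Removes every reticulation edge outside `Y` and contracts the result to a
#' binary species tree on the network's label set. For tree-child networks no
#' unlabeled leaves arise; for relaxed networks reticulations that lose their
#' only child are pruned as unlabeled leaves.
#'
#' @param net a `phylo_network`
#' @param Y a perfect set (data.frame from [perfect_sets()] or eid vector).
#' @param scan_seed internal: randomizes rewrite scan order (confluence tests).
#' @return a `displayed_tree` (a `gene_tree` on the network labels) with
#'   attributes `perfect` (the inducing set) and `orig_id`.
#' @export
display_tree <- function(net, Y, scan_seed = NULL) {
  eids <- check_perfect(net, Y)
  drop <- setdiff(net$retic_edges$eid, eids)
  st <- rw_fixpoint(rw_remove_eids(rw_state(net), drop), scan_seed = scan_seed)
  tr <- rw_to_tree(st)
  if (!setequal(leaf_labels(tr), net_labels(net)) ||
      anyDuplicated(leaf_labels(tr)))
    stop_input("displayed tree is not a tree on the network's label set")
  attr(tr, "perfect") <- Y
  class(tr) <- c("displayed_tree", class(tr))
  tr
}

#' Prune a single reticulation edge (the network N_e)
#'
#' Removes `e` and contracts all semi-binary nodes. Node and edge ids are
#' stable: surviving reticulation edges keep the edge ids they had in `net`,
#' so results computed on the pruned network can be lifted back.
#'
#' @param net a `phylo_network`
#' @param e a reticulation edge (`c(tail, head)` or one-row data.frame).
#' @return a `phylo_network` with fewer reticulations.
#' @export
prune_edge <- function(net, e) {
  eid <- find_retic_eid(net, e)
  st <- rw_fixpoint(rw_remove_eids(rw_state(net), eid))
  rw_to_network(st, times = net$times)
}

#' All trees displayed by a network
#'
#' One tree per perfect set; with `dedupe = TRUE` only distinct topologies
#' (canonical-form equality) are kept.
#'
#' @param net a `phylo_network`
#' @param dedupe drop duplicate topologies?
#' @param cap reticulation cap (default 16).
#' @return list of `displayed_tree` objects.
#' @export
displayed_trees <- function(net, dedupe = FALSE, cap = 16L) {
  trees <- lapply(perfect_sets(net, cap = cap), function(Y)
    display_tree(net, Y))
  if (dedupe) {
    keys <- vapply(trees, serialize_newick, character(1))
    trees <- trees[!duplicated(keys)]
  }
  trees
}

#' Complete a conflict-free used-edge set to a perfect set
#'
#' Keeps every directly or potentially used edge and, for each reticulation
#' untouched by the set, adds its incoming edge with the lower tail node id.
#'
#' @param net a `phylo_network`
#' @param used a used-edge set (data.frame with `eid`, e.g. from [dp_dc()]),
#'   or an eid vector.
#' @return an `odt_perfect_set` data.frame.
#' @export
complete_perfect <- function(net, used) {
  eids <- unique(if (is.data.frame(used)) used$eid else as.integer(used))
  re <- net$retic_edges
  eids <- eids[eids %in% re$eid]
  heads <- re$head[match(eids, re$eid)]
  if (anyDuplicated(heads))
    stop_input("used set has a conflict; it cannot be completed")
  for (r in setdiff(net$retic, heads)) {
    cand <- re[re$head == r, , drop = FALSE]
    eids <- c(eids, cand$eid[which.min(cand$tail)])
  }
  Y <- re[match(sort(eids), re$eid), , drop = FALSE]
  rownames(Y) <- NULL
  structure(Y, class = c("odt_perfect_set", "data.frame"))
}
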