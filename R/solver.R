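# Exact optimal-displayed-tree (ODT) solvers: conflict-resolution recursion,
# depth-bounded lower/upper bounds, the per-blob level-k solver, and the
# naive enumeration baseline.
#
# Branching: when the DP's used set has a conflict {e, e'}, the optimum over
# displayed trees is the better of the two pruned instances N_e and N_e'
# (removing e forces the sibling e'). Edge ids are stable under pruning, so
# a winning switching found deep in the recursion is expressed directly in
# the input network's reticulation edges.

dp_of <- function(cost) if (cost == "DC") dp_dc else dp_dup
tree_cost_of <- function(cost) if (cost == "DC") dc_cost else dup_cost

first_conflict <- function(used, net) {
  confs <- usage_conflicts(used, net)
  if (!length(confs)) return(NULL)
  confs[[1]]
}

new_odt_result <- function(net, cost, value, yeids, stats, variant) {
  if (!is.finite(value)) {
    return(structure(list(cost = Inf, tree = NULL, perfect = NULL,
                          stats = stats, variant = variant, cost_fun = cost),
                     class = "odt_result"))
  }
  Y <- complete_perfect(net, yeids)
  tree <- display_tree(net, Y)
  structure(list(cost = as.integer(value), tree = tree, perfect = Y,
                 stats = stats, variant = variant, cost_fun = cost),
            class = "odt_result")
}

#' Exact optimal displayed tree by conflict resolution
#'
#' Runs the scenario DP; if the backtracked used set is conflict-free its
#' score is the optimal displayed-tree cost and the completed switching
#' yields a witness tree. Otherwise the first conflict (by reticulation node
#' id) is branched: each of its two edges is pruned in turn and the better
#' sub-solution wins. At most `2^(r+1)-1` DP invocations are needed.
#'
#' @param G a `gene_tree`
#' @param net a tree-child or relaxed `phylo_network`
#' @param cost `"DC"` (deep coalescence) or `"DUP"` (duplication)
#' @param mode passed to the DP (`"auto"`, `"treechild"`, `"relaxed"`)
#' @param hybrid_threshold when the current network has at most this many
#'   reticulations, fall back to naive enumeration (0 disables; enumeration
#'   pays off for small r).
#' @param tiebreak DP backtracking tie-break (see [dp_dc()])
#' @return an `odt_result`: `cost`, `tree` (a `displayed_tree`), `perfect`
#'   (the inducing switching of the input network), `stats`
#'   (`dp_invocations`, `max_depth`, `conflicts_branched`), `variant`.
#' @export
solve_odt <- function(G, net, cost = c("DC", "DUP"), mode = "auto",
                      hybrid_threshold = 0L, tiebreak = "deep") {
  cost <- match.arg(cost)
  mode <- resolve_mode(net, mode)
  dpfun <- dp_of(cost)
  stats <- new.env(parent = emptyenv())
  stats$dp <- 0L
  stats$depth <- 0L
  stats$branched <- 0L
  rec <- function(ncur, depth) {
    stats$depth <- max(stats$depth, depth)
    if (hybrid_threshold > 0L && n_reticulations(ncur) <= hybrid_threshold &&
        n_reticulations(ncur) > 0L) {
      nv <- naive_odt(G, ncur, cost)
      return(list(value = nv$cost, yeids = nv$perfect$eid))
    }
    stats$dp <- stats$dp + 1L
    res <- dpfun(G, ncur, mode = mode, tiebreak = tiebreak)
    conf <- first_conflict(res$used, ncur)
    if (is.null(conf)) {
      if (!is.finite(res$score))
        return(list(value = Inf, yeids = integer(0)))
      Y <- complete_perfect(ncur, res$used)
      return(list(value = res$score, yeids = Y$eid))
    }
    stats$branched <- stats$branched + 1L
    e1 <- conf[1, ]
    e2 <- conf[2, ]
    a <- rec(prune_edge(ncur, e1), depth + 1L) # trees avoiding e1 (use e2)
    b <- rec(prune_edge(ncur, e2), depth + 1L)
    if (a$value <= b$value) list(value = a$value, yeids = c(a$yeids, e2$eid))
    else list(value = b$value, yeids = c(b$yeids, e1$eid))
  }
  out <- rec(net, 0L)
  new_odt_result(net, cost, out$value, out$yeids,
                 list(dp_invocations = stats$dp, max_depth = stats$depth,
                      conflicts_branched = stats$branched),
                 variant = "conflict-resolution")
}

#' Naive optimal displayed tree by full enumeration
#'
#' Minimum tree cost over all `2^r` perfect sets; the argmin is the first
#' optimum in enumeration order.
#'
#' @inheritParams solve_odt
#' @param cap reticulation cap for enumeration (default 16)
#' @return an `odt_result` (with `stats$trees_evaluated`)
#' @export
naive_odt <- function(G, net, cost = c("DC", "DUP"), cap = 16L) {
  cost <- match.arg(cost)
  cf <- tree_cost_of(cost)
  ys <- perfect_sets(net, cap = cap)
  best <- Inf
  besty <- NULL
  for (Y in ys) {
    v <- cf(G, display_tree(net, Y))
    if (v < best) {
      best <- v
      besty <- Y
    }
  }
  new_odt_result(net, cost, best, besty$eid,
                 list(dp_invocations = 0L, trees_evaluated = length(ys)),
                 variant = "naive")
}

#' Lower and upper bounds for the optimal displayed-tree cost
#'
#' The conflict-resolution recursion cut off at `maxdepth`. At a cutoff node
#' with a conflicted used set, the DP score is a valid lower bound and the
#' cost of the displayed tree obtained by deterministically resolving every
#' conflict (keep the lower-tail edge, drop its sibling, complete) is a
#' valid upper bound; internal nodes combine children by taking minima of
#' both bounds. `maxdepth = Inf` reproduces the exact solver.
#'
#' @inheritParams solve_odt
#' @param maxdepth nonnegative recursion depth cap (may be `Inf`)
#' @return an `odt_bounds_result`: `lower`, `upper`, `exact`, `stats`
#' @export
odt_bounds <- function(G, net, maxdepth = 0, cost = c("DC", "DUP"),
                       mode = "auto", tiebreak = "deep") {
  cost <- match.arg(cost)
  mode <- resolve_mode(net, mode)
  dpfun <- dp_of(cost)
  cf <- tree_cost_of(cost)
  stats <- new.env(parent = emptyenv())
  stats$dp <- 0L
  rec <- function(ncur, depth) {
    stats$dp <- stats$dp + 1L
    res <- dpfun(G, ncur, mode = mode, tiebreak = tiebreak)
    conf <- first_conflict(res$used, ncur)
    if (is.null(conf)) return(c(res$score, res$score))
    if (depth >= maxdepth) {
      # resolve every conflict toward the lower-tail edge, then complete
      eids <- unique(res$used$eid)
      for (cc in usage_conflicts(res$used, ncur)) {
        keep <- cc$eid[which.min(cc$tail)]
        eids <- setdiff(eids, setdiff(cc$eid, keep))
      }
      Y <- complete_perfect(ncur, eids)
      u <- cf(G, display_tree(ncur, Y))
      return(c(res$score, u))
    }
    a <- rec(prune_edge(ncur, conf[1, ]), depth + 1L)
    b <- rec(prune_edge(ncur, conf[2, ]), depth + 1L)
    pmin(a, b)
  }
  lu <- rec(net, 0)
  structure(list(lower = lu[1], upper = lu[2], exact = lu[1] == lu[2],
                 stats = list(dp_invocations = stats$dp)),
            class = "odt_bounds_result")
}

#' @export
print.odt_bounds_result <- function(x, ...) {
  cat(sprintf("cost bounds: [%s, %s]%s (%d DP invocations)\n",
              format(x$lower), format(x$upper),
              if (x$exact) " exact" else "", x$stats$dp_invocations))
  invisible(x)
}

# --- level-k per-blob solver ------------------------------------------------

# Extract the subnetwork rooted at v (same id space, in-edge of v dropped).
subnetwork_at <- function(net, v) {
  reach <- rep(FALSE, net$n)
  reach[v] <- TRUE
  for (w in net$topo) {
    if (!reach[w]) next
    reach[net$children[[w]]] <- TRUE
  }
  new_phylo_network(net$children, net$label, v,
                    eid = net$eid, alive = net$alive & reach)
}

# Maximal gene subtrees whose label set fits inside `labs`.
gene_forest_roots <- function(G, labs) {
  sets <- gt_label_sets(G)
  ok <- vapply(sets, function(s) all(s %in% labs), logical(1))
  which(ok & (is.na(G$parent) | !ok[ifelse(is.na(G$parent), 1L, G$parent)]))
}

# Conflict-resolution on one blob subnetwork under the forest DC-up
# objective: sum over maximal fitting gene subtrees t of
# (-|E(G|t)| + deltaup(t, sub.root)), usages unioned.
blob_solve <- function(G, sub, forest, mode, tiebreak, stats) {
  rec <- function(ncur) {
    stats$dp <- stats$dp + 1L
    eng <- dp_engine_dc(G, ncur, tiebreak)
    vals <- eng$deltaup[forest, ncur$root]
    edges_below <- vapply(forest, function(t)
      length(post_order(G$children, t)) - 1L, integer(1))
    score <- sum(vals - edges_below)
    us <- usage_empty()
    if (is.finite(score)) {
      for (t in forest) us <- usage_union(us, eng$uup(t, ncur$root))
    }
    used <- usage_to_df(ncur, us)
    conf <- first_conflict(used, ncur)
    if (is.null(conf)) {
      Y <- complete_perfect(ncur, used)
      return(list(value = score, yeids = Y$eid))
    }
    a <- rec(prune_edge(ncur, conf[1, ]))
    b <- rec(prune_edge(ncur, conf[2, ]))
    if (a$value <= b$value) list(value = a$value, yeids = c(a$yeids, conf$eid[2]))
    else list(value = b$value, yeids = c(b$yeids, conf$eid[1]))
  }
  rec(sub)
}

#' Optimal displayed tree via per-blob (level-k) decomposition
#'
#' Processes the nontrivial biconnected components (blobs) bottom-up. Each
#' non-root blob chooses the switching of its reticulations minimizing the
#' rooted (DC-up) objective of the maximal gene subtrees that fit inside the
#' blob's label set, by conflict resolution restricted to the blob; lower
#' blobs are already replaced by their chosen subtrees. The component
#' containing the network root (or the final reticulation-free remainder)
#' is solved with the ordinary objective, giving the overall cost. The
#' result always equals [solve_odt()]'s.
#'
#' @inheritParams solve_odt
#' @return an `odt_result` (with per-blob invocation counts in `stats`)
#' @export
solve_levelk <- function(G, net, cost = "DC", mode = "auto",
                         tiebreak = "deep") {
  stopifnot(cost == "DC")
  mode <- resolve_mode(net, mode)
  dec <- decompose_blobs(net)
  stats <- new.env(parent = emptyenv())
  stats$dp <- 0L
  per_blob <- integer(0)
  ncur <- net
  keep_eids <- integer(0)
  for (bi in dec$bottom_up) {
    b <- dec$blobs[[bi]]
    if (b$root == net$root) next # root blob: ordinary objective below
    sub <- subnetwork_at(ncur, b$root)
    forest <- gene_forest_roots(G, net_labels(sub))
    before <- stats$dp
    sel <- if (length(forest)) {
      blob_solve(G, sub, forest, mode, tiebreak, stats)
    } else {
      # no gene subtree reaches into the blob: any switching works
      list(value = 0, yeids = complete_perfect(sub, integer(0))$eid)
    }
    per_blob <- c(per_blob, stats$dp - before)
    # complete to a perfect set of the blob subnetwork so that reticulations
    # that vanished inside the recursion (relaxed cascades) keep one in-edge
    sel$yeids <- complete_perfect(
      sub, sel$yeids[sel$yeids %in% sub$retic_edges$eid])$eid
    keep_eids <- c(keep_eids, sel$yeids)
    drop <- setdiff(sub$retic_edges$eid, sel$yeids)
    st <- rw_fixpoint(rw_remove_eids(rw_state(ncur), drop))
    ncur <- rw_to_network(st)
  }
  fin <- solve_odt(G, ncur, cost = cost, mode = mode, tiebreak = tiebreak)
  stats$dp <- stats$dp + fin$stats$dp_invocations
  per_blob <- c(per_blob, fin$stats$dp_invocations)
  yeids <- c(keep_eids, if (!is.null(fin$perfect)) fin$perfect$eid)
  new_odt_result(net, cost, fin$cost, yeids,
                 list(dp_invocations = stats$dp, per_blob = per_blob),
                 variant = "level-k")
}

#' @export
print.odt_result <- function(x, ...) {
  cat(sprintf("optimal displayed tree (%s, %s): cost %s\n",
              x$cost_fun, x$variant, format(x$cost)))
  if (!is.null(x$tree)) cat(" ", serialize_newick(x$tree), "\n")
  if (!is.null(x$stats$dp_invocations))
    cat("  DP invocations:", x$stats$dp_invocations, "\n")
  invisible(x)
}
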