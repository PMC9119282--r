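# Ground-truth machinery, usable at small scale only: explicit network
# unfolding, exhaustive scenario enumeration with edge-type scoring, and the
# cubic first-formulation DP. These are the independent oracles the efficient
# DP is verified against.

#' Unfold a network into its path tree
#'
#' Iteratively duplicates every reticulation subtree so that nodes of the
#' result correspond one-to-one to directed root-node paths of the network.
#' Reticulation copies appear as semi-binary (outdegree-1) nodes.
#'
#' @param net a `phylo_network`
#' @param cap maximum reticulation count (the unfolding may be exponential)
#' @param max_nodes hard guard on the unfolded size
#' @return list of class `odt_unfolded`: parallel vectors `orig` (origin node
#'   in `net`), `parent`, `eid` (origin edge id of the in-edge), `label`,
#'   `depth`, `copy_index` (per-label counter), children list `kids`, `root`,
#'   and the source network `net`.
#' @export
unfold_network <- function(net, cap = 8L, max_nodes = 200000L) {
  if (n_reticulations(net) > cap)
    stop_cap("unfolding capped at r <= %d reticulations", cap)
  # size check: number of unfolded nodes = number of root-v paths, summed
  paths <- numeric(net$n)
  paths[net$root] <- 1
  for (v in net$topo) for (w in net$children[[v]])
    paths[w] <- paths[w] + paths[v]
  if (sum(paths) > max_nodes)
    stop_cap("unfolded network would have %d nodes (cap %d)",
             sum(paths), max_nodes)

  orig <- integer(0); parent <- integer(0); eid <- integer(0)
  label <- character(0); depth <- integer(0)
  kids <- list()
  grow <- function(v, p, e, d) {
    id <- length(orig) + 1L
    orig[id] <<- v; parent[id] <<- p; eid[id] <<- e
    label[id] <<- net$label[v]; depth[id] <<- d
    kids[[id]] <<- integer(0)
    ch <- net$children[[v]]
    for (i in seq_along(ch)) {
      cid <- grow(ch[i], id, net$eid[[v]][i], d + 1L)
      kids[[id]] <<- c(kids[[id]], cid)
    }
    id
  }
  root <- grow(net$root, NA_integer_, NA_integer_, 0L)
  copy_index <- integer(length(orig))
  for (lb in unique(label[!is.na(label)])) {
    w <- which(!is.na(label) & label == lb)
    copy_index[w] <- seq_along(w)
  }
  structure(list(orig = orig, parent = parent, eid = eid, label = label,
                 depth = depth, copy_index = copy_index, kids = kids,
                 root = root, net = net),
            class = "odt_unfolded")
}

hat_lca <- function(U, a, b) {
  while (a != b) {
    if (U$depth[a] >= U$depth[b]) a <- U$parent[a] else b <- U$parent[b]
  }
  a
}

# Scenario = integer vector over V(G): for gene leaves, the unfolded leaf
# chosen; extended to internal nodes by the lca in the unfolded tree.
scenario_extend <- function(G, U, xi_leaves) {
  m <- integer(G$n)
  for (g in G$postorder) {
    m[g] <- if (G$is_leaf[g]) xi_leaves[g]
      else hat_lca(U, m[G$children[[g]][1]], m[G$children[[g]][2]])
  }
  m
}

#' Enumerate all scenarios for a gene tree and an unfolded network
#'
#' A scenario maps every gene leaf to a same-labeled leaf of the unfolded
#' network; the full Cartesian product over per-leaf copy lists is produced
#' in deterministic order (leaves by gene node id; copies by unfolded id,
#' first copy fastest).
#'
#' @param G a `gene_tree`
#' @param U an `odt_unfolded` (from [unfold_network()])
#' @param cap maximum number of scenarios
#' @return list of integer vectors (indexed by gene node id, leaf slots set)
#' @export
enumerate_scenarios <- function(G, U, cap = 1e6) {
  nsc <- count_scenarios(G, U)
  if (nsc == 0) stop_input("a gene label has no copy in the unfolded network")
  if (nsc > cap) stop_cap("%g scenarios exceed the cap (%g)", nsc, cap)
  leaves <- which(G$is_leaf)
  copies <- lapply(leaves, function(g) which(!is.na(U$label) &
                                             U$label == G$label[g]))
  idx <- rep(1L, length(leaves))
  out <- vector("list", nsc)
  for (i in seq_len(nsc)) {
    xi <- integer(G$n)
    xi[leaves] <- mapply(function(cp, j) cp[j], copies, idx)
    out[[i]] <- xi
    j <- 1L
    while (j <= length(leaves)) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= length(copies[[j]])) break
      idx[j] <- 1L
      j <- j + 1L
    }
  }
  out
}

count_scenarios <- function(G, U) {
  leaves <- which(G$is_leaf)
  prod(vapply(leaves, function(g)
    sum(!is.na(U$label) & U$label == G$label[g]), numeric(1)))
}

# Walk one gene edge <v,w>: classify visited unfolded edges into types
# I-IV, count types I/II (kappa) and record bypassed reticulation eids.
walk_gene_edge <- function(U, from, to) {
  is_ret <- U$net$kind == "reticulation"
  path <- integer(0)
  b <- to
  while (b != from) {
    path <- c(b, path)
    b <- U$parent[b]
  }
  kappa <- 0L
  types <- character(length(path))
  direct <- integer(0)
  bypassed <- integer(0)
  a <- from
  for (i in seq_along(path)) {
    b <- path[i]
    if (i == 1L) {
      types[i] <- "I"
    } else if (length(U$kids[[a]]) == 2L) {
      sib <- setdiff(U$kids[[a]], b)
      types[i] <- if (is_ret[U$orig[sib]]) "III" else "II"
      if (types[i] == "III") bypassed <- c(bypassed, U$eid[sib])
    } else {
      types[i] <- "IV"
    }
    if (types[i] %in% c("I", "II")) {
      kappa <- kappa + 1L
      if (is_ret[U$orig[b]]) direct <- c(direct, U$eid[b])
    }
    a <- b
  }
  list(kappa = kappa, types = types, direct = direct, bypassed = bypassed)
}

#' Deep coalescence score of a scenario
#'
#' Sum over gene edges of (number of visited Type I/II edges, minus one),
#' with a per-edge type trace and the list of bypassed reticulation edges.
#'
#' @param G a `gene_tree`
#' @param U an `odt_unfolded`
#' @param xi a scenario (from [enumerate_scenarios()])
#' @return list: `score`, `trace` (per gene edge), `direct` / `bypassed`
#'   (origin eids), `m` (the lca-extension, unfolded node per gene node)
#' @export
scenario_dc_score <- function(G, U, xi) {
  m <- scenario_extend(G, U, xi)
  score <- 0L
  trace <- list()
  direct <- integer(0)
  bypassed <- integer(0)
  for (v in seq_len(G$n)) {
    for (w in G$children[[v]]) {
      res <- walk_gene_edge(U, m[v], m[w])
      score <- score + res$kappa - 1L
      trace[[length(trace) + 1L]] <-
        list(edge = c(v, w), kappa = res$kappa, types = res$types)
      direct <- c(direct, res$direct)
      bypassed <- c(bypassed, res$bypassed)
    }
  }
  list(score = score, trace = trace, direct = unique(direct),
       bypassed = unique(bypassed), m = m)
}

#' Used reticulation edges of a scenario
#'
#' An edge is directly used when some visited Type I/II edge maps onto it,
#' and potentially used when its sibling is bypassed. A conflict is a pair
#' of sibling edges both present.
#'
#' @inheritParams scenario_dc_score
#' @return data.frame of class `odt_used_edges` (tail, head, eid, direct,
#'   potential) with attribute `conflict`.
#' @export
scenario_used <- function(G, U, xi) {
  sc <- scenario_dc_score(G, U, xi)
  net <- U$net
  re <- net$retic_edges
  pot <- vapply(sc$bypassed, function(e) {
    h <- re$head[re$eid == e]
    re$eid[re$head == h & re$eid != e]
  }, integer(1))
  make_used_edges(net, direct = sc$direct, potential = pot)
}

make_used_edges <- function(net, direct = integer(0),
                            potential = integer(0)) {
  re <- net$retic_edges
  eids <- sort(unique(c(direct, potential)))
  out <- re[match(eids, re$eid), , drop = FALSE]
  out$direct <- eids %in% direct
  out$potential <- eids %in% potential
  rownames(out) <- NULL
  conf <- anyDuplicated(out$head) > 0L
  structure(out, class = c("odt_used_edges", "data.frame"), conflict = conf)
}

#' Duplication score of a scenario
#'
#' Number of internal gene nodes whose lca-extension image equals a child's.
#'
#' @inheritParams scenario_dc_score
#' @return nonnegative integer
#' @export
scenario_dup_score <- function(G, U, xi) {
  m <- scenario_extend(G, U, xi)
  total <- 0L
  for (g in which(!G$is_leaf)) {
    ch <- G$children[[g]]
    if (m[g] == m[ch[1]] || m[g] == m[ch[2]]) total <- total + 1L
  }
  total
}

#' Exhaustive optimal-scenario search (oracle)
#'
#' Enumerates every scenario and returns the exact minimum score, the used
#' set of the first optimum, whether some optimal scenario is regular
#' (conflict-free), and optionally the used sets of all optima.
#'
#' @param G a `gene_tree`
#' @param net a `phylo_network`
#' @param cost `"DC"` or `"DUP"`
#' @param cap scenario-count cap
#' @param keep_all_used also return the used sets of every optimal scenario?
#' @return list: `score`, `used`, `regular_exists`, optionally `all_used`
#' @export
best_scenario_bruteforce <- function(G, net, cost = c("DC", "DUP"),
                                     cap = 1e6, keep_all_used = FALSE) {
  cost <- match.arg(cost)
  U <- unfold_network(net)
  xis <- enumerate_scenarios(G, U, cap = cap)
  best <- Inf
  best_used <- NULL
  regular <- FALSE
  all_used <- list()
  for (xi in xis) {
    s <- if (cost == "DC") scenario_dc_score(G, U, xi)$score
         else scenario_dup_score(G, U, xi)
    if (s > best) next
    u <- scenario_used(G, U, xi)
    if (s < best) {
      best <- s
      best_used <- u
      regular <- !attr(u, "conflict")
      all_used <- list(u)
    } else {
      regular <- regular || !attr(u, "conflict")
      if (keep_all_used) all_used <- c(all_used, list(u))
    }
  }
  out <- list(score = best, used = best_used, regular_exists = regular)
  if (keep_all_used) out$all_used <- all_used
  out
}

#' Scenario induced by a perfect set
#'
#' Masks the unfolded tree: edges whose origin is a removed reticulation
#' edge are cut, and every gene leaf maps to its unique surviving copy.
#'
#' @param G a `gene_tree`
#' @param U an `odt_unfolded`
#' @param Y a perfect set of `U$net`
#' @return a scenario vector usable with the `scenario_*` functions
#' @export
scenario_from_perfect <- function(G, U, Y) {
  eids <- check_perfect(U$net, Y)
  drop <- setdiff(U$net$retic_edges$eid, eids)
  ok <- rep(FALSE, length(U$orig))
  ok[U$root] <- TRUE
  ord <- order(U$depth)
  for (v in ord) {
    if (!ok[v]) next
    for (w in U$kids[[v]]) if (!(U$eid[w] %in% drop)) ok[w] <- TRUE
  }
  xi <- integer(G$n)
  for (g in which(G$is_leaf)) {
    cand <- which(ok & !is.na(U$label) & U$label == G$label[g])
    if (length(cand) != 1L)
      stop_input("label '%s' has %d surviving copies under Y",
                 G$label[g], length(cand))
    xi[g] <- cand
  }
  xi
}

# --- cubic first-formulation DP --------------------------------------------

#' Optimal scenario score by the cubic dynamic program (oracle)
#'
#' The first DP formulation: delta over gene node x network node with the
#' path-cost table pi minimized over all descendant pairs. Cubic in the
#' network size; tree-child networks only. Used as an independent
#' cross-check of the efficient DP.
#'
#' @param G a `gene_tree`
#' @param net a tree-child `phylo_network`
#' @return integer scenario score (also the DC lower bound)
#' @export
dc_score_cubic <- function(G, net) {
  is_ret <- net$kind == "reticulation"
  n <- net$n
  pi_memo <- matrix(NA_real_, n, n)
  has_edge <- function(s, t) any(net$children[[s]] == t)
  pi_fun <- function(s, t) {
    if (s == t) return(0)
    if (!is.na(pi_memo[s, t])) return(pi_memo[s, t])
    val <- if (has_edge(s, t)) {
      1
    } else if (is_ret[t]) {
      1 + min(vapply(net$parents[[t]], function(p) pi_fun(s, p), numeric(1)))
    } else if (t == net$root) {
      Inf
    } else {
      p <- net$parents[[t]][1]
      sib <- setdiff(net$children[[p]], t)
      if (is_ret[p] || (length(sib) && any(is_ret[sib]))) {
        pi_fun(s, p) # Type III/IV: free passage
      } else {
        1 + pi_fun(s, p) # Type II
      }
    }
    pi_memo[s, t] <<- val
    val
  }
  live <- net$topo
  non_ret <- live[!is_ret[live]]
  delta <- matrix(Inf, G$n, n)
  for (g in G$postorder) {
    if (G$is_leaf[g]) {
      for (s in non_ret) {
        if (net$outdeg[s] == 0L && identical(net$label[s], G$label[g]))
          delta[g, s] <- 0
      }
    } else {
      ch <- G$children[[g]]
      for (s in non_ret) {
        best1 <- Inf
        best2 <- Inf
        for (t in non_ret) {
          pv <- pi_fun(s, t)
          if (is.finite(pv)) {
            best1 <- min(best1, delta[ch[1], t] + pv)
            best2 <- min(best2, delta[ch[2], t] + pv)
          }
        }
        delta[g, s] <- best1 + best2
      }
    }
  }
  as.integer(-n_edges(G) + min(delta[G$root, non_ret]))
}
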