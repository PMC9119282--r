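# Efficient O(|G||N|) dynamic programs for the deep coalescence and
# duplication scenario scores, with usage-rule backtracking.
#
# Three tables over V(G) x V(N):
#   delta    - minimum number of Type I/II edges for G|g with the image of g
#              fixed at s (undefined/Inf when s is a reticulation),
#   deltaf   - delta with the cost of the edge entering g included
#              ("first-edge" table; s a tree node),
#   deltaup  - image of g anywhere at or below s.
# tau(s) is 0 for reticulations and 1 otherwise; the reticulation case of the
# deltaup recursion is written as tau(child) + deltaup(child), which equals
# the tree-child form (the child of a reticulation is never a reticulation
# there) and is the correct relaxed form otherwise.

net_class_flags <- function(net) {
  live <- which(net$alive)
  k <- net$kind
  is_ret <- k == "reticulation"
  ok_bin <- all(vapply(live, function(v) {
    switch(k[v],
      root = net$indeg[v] == 0L && net$outdeg[v] == 2L,
      leaf = net$indeg[v] == 1L && net$outdeg[v] == 0L,
      reticulation = net$indeg[v] == 2L && net$outdeg[v] == 1L,
      tree = net$indeg[v] == 1L && net$outdeg[v] == 2L,
      FALSE)
  }, logical(1)))
  leaves <- live[net$outdeg[live] == 0L]
  list(
    is_binary = ok_bin,
    labels_one_to_one = !anyNA(net$label[leaves]) &&
      !anyDuplicated(net$label[leaves]),
    is_tree_child = all(vapply(live[net$outdeg[live] > 0L], function(v)
      any(!is_ret[net$children[[v]]]), logical(1))),
    is_relaxed = all(vapply(live, function(v)
      sum(is_ret[net$children[[v]]]) <= 1L, logical(1)))
  )
}

resolve_mode <- function(net, mode = c("auto", "treechild", "relaxed")) {
  mode <- match.arg(mode)
  fl <- net_class_flags(net)
  if (!fl$is_binary) stop_class("network is not binary")
  if (!fl$labels_one_to_one) stop_class("network labels are not one-to-one")
  if (mode == "auto") mode <- if (fl$is_tree_child) "treechild"
    else if (fl$is_relaxed) "relaxed"
    else stop_class("network is neither tree-child nor relaxed")
  if (mode == "treechild" && !fl$is_tree_child)
    stop_class("not a tree-child network")
  if (mode == "relaxed" && !fl$is_relaxed)
    stop_class("not a relaxed network")
  mode
}

# usage sets: list(direct = eids, potential = eids)
usage_empty <- function() list(direct = integer(0), potential = integer(0))
usage_union <- function(...) {
  us <- list(...)
  list(direct = sort(unique(unlist(lapply(us, `[[`, "direct")))),
       potential = sort(unique(unlist(lapply(us, `[[`, "potential")))))
}
usage_key <- function(u) sort(unique(c(u$direct, u$potential)))
usage_less <- function(a, b) {
  ka <- usage_key(a); kb <- usage_key(b)
  m <- min(length(ka), length(kb))
  if (m > 0) {
    d <- which(ka[seq_len(m)] != kb[seq_len(m)])
    if (length(d)) return(ka[d[1]] < kb[d[1]])
  }
  length(ka) < length(kb)
}
usage_to_df <- function(net, u) {
  make_used_edges(net, direct = u$direct, potential = u$potential)
}

# rho / rho-bar: the one-element usage with <s,c> (resp. its sibling) when
# <s,c> is a reticulation edge, else empty.
rho_eid <- function(net, s, c) {
  if (net$kind[c] != "reticulation") return(NA_integer_)
  i <- which(net$children[[s]] == c)[1]
  net$eid[[s]][i]
}
rhobar_eid <- function(net, s, c) {
  e <- rho_eid(net, s, c)
  if (is.na(e)) return(NA_integer_)
  re <- net$retic_edges
  re$eid[re$head == c & re$eid != e][1]
}
as_usage <- function(direct = NA_integer_, potential = NA_integer_) {
  list(direct = direct[!is.na(direct)], potential = potential[!is.na(potential)])
}

gt_levels <- function(G) {
  h <- integer(G$n)
  for (v in G$postorder) {
    if (!G$is_leaf[v]) h[v] <- 1L + max(h[G$children[[v]]])
  }
  split(seq_len(G$n), h)
}

# --- DC engine --------------------------------------------------------------

dp_engine_dc <- function(G, net, tiebreak = c("deep", "min-usage")) {
  tiebreak <- match.arg(tiebreak)
  nG <- G$n
  nN <- net$n
  ls <- gt_leaf_summary(G)
  levels <- gt_levels(G)
  gcl <- vapply(seq_len(nG), function(v)
    if (G$is_leaf[v]) NA_integer_ else G$children[[v]][1], integer(1))
  gcr <- vapply(seq_len(nG), function(v)
    if (G$is_leaf[v]) NA_integer_ else G$children[[v]][2], integer(1))
  tau <- ifelse(net$kind == "reticulation", 0, 1)
  is_ret <- net$kind == "reticulation"
  is_nleaf <- net$alive & net$outdeg == 0L

  delta <- matrix(Inf, nG, nN)
  deltaf <- matrix(Inf, nG, nN)
  deltaup <- matrix(Inf, nG, nN)

  for (s in rev(net$topo)) {
    if (is_nleaf[s]) {
      col <- ifelse(!is.na(ls$ulab) & ls$ulab == net$label[s], 0, Inf)
      delta[, s] <- col
      deltaup[, s] <- col
    } else if (is_ret[s]) {
      c1 <- net$children[[s]][1]
      deltaup[, s] <- tau[c1] + deltaup[, c1]
    } else {
      ch <- sort(net$children[[s]])
      c1 <- ch[1]; c2 <- ch[2]
      dstar <- pmin(tau[c1] + deltaup[, c1], tau[c2] + deltaup[, c2])
      fvec <- rep(Inf, nG)
      for (lv in levels) {
        internal <- lv[!G$is_leaf[lv]]
        if (length(internal)) {
          delta[internal, s] <-
            fvec[gcl[internal]] + fvec[gcr[internal]]
        }
        fvec[lv] <- pmin(delta[lv, s], dstar[lv])
      }
      deltaf[, s] <- fvec
      deltaup[, s] <- pmin(delta[, s],
                           tau[c1] * tau[c2] + pmin(deltaup[, c1],
                                                    deltaup[, c2]))
    }
  }

  memo <- new.env(parent = emptyenv())
  pick_branch <- function(stop_val, stop_fun, cands, cand_fun) {
    # cands: node ids whose branch attains the cell value
    if (tiebreak == "deep") {
      if (length(cands)) return(cand_fun(cands[1]))
      return(stop_fun())
    }
    opts <- lapply(cands, cand_fun)
    if (isTRUE(stop_val)) opts <- c(opts, list(stop_fun()))
    best <- opts[[1]]
    for (o in opts[-1]) if (usage_less(o, best)) best <- o
    best
  }
  u_fun <- function(g, s) {
    key <- paste0("u", g, ".", s)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (G$is_leaf[g] || is_nleaf[s] || !is.finite(delta[g, s])) {
      usage_empty()
    } else {
      usage_union(uf_fun(gcl[g], s), uf_fun(gcr[g], s))
    }
    memo[[key]] <- val
    val
  }
  uf_fun <- function(g, s) {
    key <- paste0("f", g, ".", s)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- deltaf[g, s]
    if (!is.finite(v)) return(memo[[key]] <- usage_empty())
    ch <- sort(net$children[[s]])
    cands <- ch[vapply(ch, function(c)
      isTRUE(all.equal(v, tau[c] + deltaup[g, c])), logical(1))]
    can_stop <- isTRUE(all.equal(v, delta[g, s]))
    val <- pick_branch(can_stop, function() u_fun(g, s), cands, function(c)
      usage_union(uup_fun(g, c), as_usage(direct = rho_eid(net, s, c))))
    memo[[key]] <- val
    val
  }
  uup_fun <- function(g, s) {
    key <- paste0("p", g, ".", s)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- deltaup[g, s]
    val <- if (!is.finite(v)) {
      usage_empty()
    } else if (is_nleaf[s]) {
      u_fun(g, s)
    } else if (is_ret[s]) {
      c1 <- net$children[[s]][1]
      usage_union(uup_fun(g, c1), as_usage(direct = rho_eid(net, s, c1)))
    } else {
      ch <- sort(net$children[[s]])
      tt <- tau[ch[1]] * tau[ch[2]]
      cands <- ch[vapply(ch, function(c)
        isTRUE(all.equal(v, tt + deltaup[g, c])), logical(1))]
      can_stop <- isTRUE(all.equal(v, delta[g, s]))
      pick_branch(can_stop, function() u_fun(g, s), cands, function(c)
        usage_union(uup_fun(g, c),
                    as_usage(direct = rho_eid(net, s, c),
                             potential = rhobar_eid(net, s, setdiff(ch, c)))))
    }
    memo[[key]] <- val
    val
  }

  list(delta = delta, deltaf = deltaf, deltaup = deltaup,
       u = u_fun, uf = uf_fun, uup = uup_fun)
}

# --- DUP engine -------------------------------------------------------------

dp_engine_dup <- function(G, net, tiebreak = c("deep", "min-usage")) {
  tiebreak <- match.arg(tiebreak)
  nG <- G$n
  nN <- net$n
  ls <- gt_leaf_summary(G)
  levels <- gt_levels(G)
  gcl <- vapply(seq_len(nG), function(v)
    if (G$is_leaf[v]) NA_integer_ else G$children[[v]][1], integer(1))
  gcr <- vapply(seq_len(nG), function(v)
    if (G$is_leaf[v]) NA_integer_ else G$children[[v]][2], integer(1))
  is_ret <- net$kind == "reticulation"
  is_nleaf <- net$alive & net$outdeg == 0L

  delta <- matrix(Inf, nG, nN)
  deltaup <- matrix(Inf, nG, nN)

  for (s in rev(net$topo)) {
    if (is_nleaf[s]) {
      match_lab <- !is.na(ls$ulab) & ls$ulab == net$label[s]
      delta[, s] <- ifelse(match_lab, ls$nleaf - 1L, Inf)
      deltaup[, s] <- delta[, s]
    } else if (is_ret[s]) {
      deltaup[, s] <- deltaup[, net$children[[s]][1]]
    } else {
      ch <- sort(net$children[[s]])
      c1 <- ch[1]; c2 <- ch[2]
      dmin <- pmin(deltaup[, c1], deltaup[, c2])
      upvec <- rep(Inf, nG)
      for (lv in levels) {
        internal <- lv[!G$is_leaf[lv]]
        if (length(internal)) {
          a <- gcl[internal]; b <- gcr[internal]
          delta[internal, s] <- pmin(
            1 + delta[a, s] + upvec[b],
            1 + delta[b, s] + upvec[a],
            deltaup[a, c1] + deltaup[b, c2],
            deltaup[a, c2] + deltaup[b, c1])
        }
        upvec[lv] <- pmin(delta[lv, s], dmin[lv])
      }
      deltaup[, s] <- upvec
    }
  }

  memo <- new.env(parent = emptyenv())
  u_fun <- function(g, s) {
    key <- paste0("u", g, ".", s)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- delta[g, s]
    val <- if (G$is_leaf[g] || is_nleaf[s] || !is.finite(v)) {
      usage_empty()
    } else {
      ch <- sort(net$children[[s]])
      c1 <- ch[1]; c2 <- ch[2]
      a <- gcl[g]; b <- gcr[g]
      eq <- function(x) isTRUE(all.equal(v, x))
      if (eq(1 + delta[a, s] + deltaup_col(s)[b])) {
        usage_union(u_fun(a, s), uup_fun(b, s))
      } else if (eq(1 + delta[b, s] + deltaup_col(s)[a])) {
        usage_union(uup_fun(a, s), u_fun(b, s))
      } else if (eq(deltaup[a, c1] + deltaup[b, c2])) {
        usage_union(uup_fun2(a, c1), uup_fun2(b, c2),
                    as_usage(direct = rho_eid(net, s, c1)),
                    as_usage(direct = rho_eid(net, s, c2)))
      } else {
        usage_union(uup_fun2(a, c2), uup_fun2(b, c1),
                    as_usage(direct = rho_eid(net, s, c1)),
                    as_usage(direct = rho_eid(net, s, c2)))
      }
    }
    memo[[key]] <- val
    val
  }
  # deltaup at a tree node s equals the stored column (upvec); the same
  # accessor works for every node kind.
  deltaup_col <- function(s) deltaup[, s]
  uup_fun <- function(g, s) uup_fun2(g, s)
  uup_fun2 <- function(g, s) {
    key <- paste0("p", g, ".", s)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- deltaup[g, s]
    val <- if (!is.finite(v)) {
      usage_empty()
    } else if (is_nleaf[s]) {
      usage_empty()
    } else if (is_ret[s]) {
      c1 <- net$children[[s]][1]
      usage_union(uup_fun2(g, c1), as_usage(direct = rho_eid(net, s, c1)))
    } else {
      ch <- sort(net$children[[s]])
      cands <- ch[vapply(ch, function(c)
        isTRUE(all.equal(v, deltaup[g, c])), logical(1))]
      can_stop <- isTRUE(all.equal(v, delta[g, s]))
      if (tiebreak == "deep") {
        if (length(cands)) {
          c <- cands[1]
          usage_union(uup_fun2(g, c), as_usage(direct = rho_eid(net, s, c)))
        } else {
          u_fun(g, s)
        }
      } else {
        opts <- lapply(cands, function(c)
          usage_union(uup_fun2(g, c), as_usage(direct = rho_eid(net, s, c))))
        if (can_stop) opts <- c(opts, list(u_fun(g, s)))
        best <- opts[[1]]
        for (o in opts[-1]) if (usage_less(o, best)) best <- o
        best
      }
    }
    memo[[key]] <- val
    val
  }

  list(delta = delta, deltaup = deltaup, u = u_fun, uup = uup_fun2)
}

# --- public DP entry points -------------------------------------------------

finish_dp <- function(G, net, eng, cost, mode) {
  live <- net$topo
  cand <- live[net$kind[live] != "reticulation"]
  vals <- eng$delta[G$root, cand]
  best <- min(vals)
  if (!is.finite(best)) {
    return(structure(list(
      score = Inf, used = make_used_edges(net), root_node = NA_integer_,
      tables = eng, mode = mode, cost = cost),
      class = "odt_dp_result"))
  }
  s_star <- cand[which(vals == best)[1]]
  offset <- if (cost == "DC") -n_edges(G) else 0L
  u <- eng$u(G$root, s_star)
  structure(list(
    score = as.integer(offset + best),
    used = usage_to_df(net, u),
    root_node = s_star,
    tables = eng, mode = mode, cost = cost), class = "odt_dp_result")
}

#' Optimal deep coalescence scenario score by dynamic programming
#'
#' Computes, in O(|G||N|) time, the minimum deep coalescence score over all
#' scenarios embedding the gene tree into the network, together with the set
#' of reticulation edges used directly or potentially by the backtracked
#' optimal scenario. The score is a lower bound on the optimal
#' displayed-tree cost, and is exact when the used set is conflict-free.
#'
#' @param G a `gene_tree`
#' @param net a tree-child or relaxed `phylo_network`
#' @param mode `"auto"` (default), `"treechild"` or `"relaxed"`; the network
#'   must belong to the requested class.
#' @param tiebreak `"deep"` (default: equal-score branches resolve toward
#'   deeper mappings) or `"min-usage"` (prefer the lexicographically
#'   smallest used set among equal-score branches).
#' @return an `odt_dp_result`: `score` (integer or `Inf` when some gene
#'   label is absent from the network), `used` (an `odt_used_edges`
#'   data.frame), `root_node` (the argmin image of the gene root), `tables`.
#' @export
dp_dc <- function(G, net, mode = "auto", tiebreak = "deep") {
  mode <- resolve_mode(net, mode)
  finish_dp(G, net, dp_engine_dc(G, net, tiebreak), "DC", mode)
}

#' Optimal duplication scenario score by dynamic programming
#'
#' The duplication analogue of [dp_dc()]: minimizes the number of gene nodes
#' mapping with a child to the same network node, over all scenarios.
#'
#' @inheritParams dp_dc
#' @return an `odt_dp_result` (see [dp_dc()]); no potential usage arises
#'   under the duplication rules.
#' @export
dp_dup <- function(G, net, mode = "auto", tiebreak = "deep") {
  mode <- resolve_mode(net, mode)
  finish_dp(G, net, dp_engine_dup(G, net, tiebreak), "DUP", mode)
}

#' Rooted deep coalescence score (DC-up)
#'
#' The minimum, over scenarios, of the score plus the path length from the
#' network root down to the image of the gene root: the quantity a non-root
#' blob contributes in the level-k solver. Computed from the `deltaup` table
#' at the network root.
#'
#' @inheritParams dp_dc
#' @return an `odt_dp_result` with the DC-up score and its used set
#' @export
dc_up_score <- function(G, net, mode = "auto", tiebreak = "deep") {
  mode <- resolve_mode(net, mode)
  eng <- dp_engine_dc(G, net, tiebreak)
  v <- eng$deltaup[G$root, net$root]
  if (!is.finite(v)) {
    return(structure(list(score = Inf, used = make_used_edges(net),
                          root_node = NA_integer_, tables = eng,
                          mode = mode, cost = "DC-up"),
                     class = "odt_dp_result"))
  }
  structure(list(
    score = as.integer(-n_edges(G) + v),
    used = usage_to_df(net, eng$uup(G$root, net$root)),
    root_node = net$root, tables = eng, mode = mode, cost = "DC-up"),
    class = "odt_dp_result")
}

#' Sibling conflicts in a used-edge set
#'
#' @param used an `odt_used_edges` data.frame (or any data.frame with `eid`)
#' @param net the `phylo_network` the edges belong to
#' @return a list of two-row data.frames, one per reticulation whose both
#'   incoming edges are present, ordered by reticulation node id.
#' @export
usage_conflicts <- function(used, net) {
  re <- net$retic_edges
  eids <- unique(used$eid)
  heads <- re$head[match(eids, re$eid)]
  bad <- sort(unique(heads[duplicated(heads)]))
  lapply(bad, function(h) {
    out <- re[re$head == h & re$eid %in% eids, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' @export
print.odt_dp_result <- function(x, ...) {
  cat(sprintf("%s scenario score: %s (mode %s)\n", x$cost,
              format(x$score), x$mode))
  cat(sprintf("  used reticulation edges: %d (%s)\n", nrow(x$used),
              if (attr(x$used, "conflict")) "conflicted" else "conflict-free"))
  invisible(x)
}
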