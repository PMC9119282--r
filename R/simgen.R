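# Random instance generation: ultrametric Yule species trees, time-consistent
# tree-child/relaxed reticulation insertion, Yule-Harding gene trees,
# displayed-tree sampling, and the R1/R2/R3-style datasets.

#' Simulate an ultrametric species tree under the Yule process
#'
#' Lineages split at exponential waiting times (rate = number of lineages),
#' the splitting lineage chosen uniformly; node times are normalized so the
#' root has time 0 and all leaves time 1. Leaves are labeled `x1..xn`.
#'
#' @param n number of leaves (>= 2)
#' @param seed optional integer seed
#' @return a `timed_tree` (a `gene_tree` with a `times` attribute)
#' @export
sim_species_tree <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n < 2) stop_input("need n >= 2 leaves")
  children <- list(integer(0))
  times <- 0
  root <- 1L
  lineages <- integer(0) # pending leaves (node ids)
  # root splits immediately into two lineages at time 0
  for (i in 1:2) {
    id <- length(children) + 1L
    children[[id]] <- integer(0)
    times[id] <- NA_real_
    children[[root]] <- c(children[[root]], id)
    lineages <- c(lineages, id)
  }
  t <- 0
  while (length(lineages) < n) {
    k <- length(lineages)
    t <- t + stats::rexp(1, rate = k)
    v <- lineages[sample.int(k, 1)]
    times[v] <- t
    lineages <- lineages[lineages != v]
    for (i in 1:2) {
      id <- length(children) + 1L
      children[[id]] <- integer(0)
      times[id] <- NA_real_
      children[[v]] <- c(children[[v]], id)
      lineages <- c(lineages, id)
    }
  }
  height <- t + stats::rexp(1, rate = n)
  times[lineages] <- height
  times <- times / height
  label <- rep(NA_character_, length(children))
  label[lineages] <- paste0("x", seq_along(lineages))
  tr <- new_gene_tree(children, label, root)
  attr(tr, "times") <- times
  class(tr) <- c("timed_tree", class(tr))
  tr
}

timed_tree_as_network <- function(tr) {
  new_phylo_network(tr$children, tr$label, tr$root,
                    times = attr(tr, "times"))
}

#' Insert reticulations into a timed species tree
#'
#' Repeats the rejection loop: pick two distinct non-reticulation edges,
#' subdivide each (the new vertex time drawn uniformly between the endpoint
#' times), add a reticulation edge from the lower-time vertex to the
#' higher-time vertex, and undo the addition when the requested class
#' (tree-child or relaxed) is violated. Leaf times never change, so every
#' displayed tree of the result is ultrametric.
#'
#' @param S a `timed_tree` from [sim_species_tree()]
#' @param k number of reticulations to add
#' @param seed optional integer seed
#' @param class `"treechild"` (default) or `"relaxed"`
#' @param budget maximum attempts per reticulation (default 1000)
#' @return a `phylo_network` with `k` reticulations (node times kept
#'   internally in `$times`)
#' @export
add_reticulations <- function(S, k, seed = NULL,
                              class = c("treechild", "relaxed"),
                              budget = 1000L) {
  class <- match.arg(class)
  if (!is.null(seed)) set.seed(seed)
  net <- timed_tree_as_network(S)
  if (k == 0) return(net)
  added <- 0L
  attempts <- 0L
  while (added < k) {
    attempts <- attempts + 1L
    if (attempts > budget * k)
      stop_cap("rejection budget exhausted after %d attempts", attempts)
    cand <- try_add_one(net, class)
    if (!is.null(cand)) {
      net <- cand
      added <- added + 1L
    }
  }
  net
}

try_add_one <- function(net, class) {
  e <- net_edges(net)
  e <- e[net$kind[e$head] != "reticulation", , drop = FALSE]
  if (nrow(e) < 2) return(NULL)
  pick <- sample.int(nrow(e), 2)
  t1 <- net$times
  sub <- function(row, children, times) {
    v <- row$tail
    w <- row$head
    nid <- length(children) + 1L
    children[[nid]] <- w
    i <- which(children[[v]] == w)[1]
    children[[v]][i] <- nid
    times[nid] <- stats::runif(1, times[v], times[w])
    list(children = children, times = times, id = nid)
  }
  s1 <- sub(e[pick[1], ], net$children, t1)
  s2 <- sub(e[pick[2], ], s1$children, s1$times)
  children <- s2$children
  times <- s2$times
  a <- s1$id
  b <- s2$id
  lo <- if (times[a] <= times[b]) a else b
  hi <- if (lo == a) b else a
  children[[lo]] <- c(children[[lo]], hi)
  label <- c(net$label, NA_character_, NA_character_)
  cand <- tryCatch(
    new_phylo_network(children, label, net$root, times = times),
    error = function(e) NULL)
  if (is.null(cand)) return(NULL)
  fl <- net_class_flags(cand)
  ok <- fl$is_binary &&
    if (class == "treechild") fl$is_tree_child else fl$is_relaxed
  if (ok) cand else NULL
}

#' Simulate a gene tree under the Yule-Harding model
#'
#' Starts from a cherry of two random labels and repeatedly replaces a
#' uniformly chosen leaf with a cherry containing the next label of a random
#' permutation.
#'
#' @param labels character vector of leaf labels (>= 2, used once each)
#' @param seed optional integer seed
#' @return a `gene_tree`
#' @export
sim_gene_tree <- function(labels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(labels) < 2) stop_input("need at least 2 labels")
  labels <- sample(labels)
  children <- list(c(2L, 3L), integer(0), integer(0))
  lab <- c(NA_character_, labels[1], labels[2])
  for (i in seq_along(labels)[-(1:2)]) {
    leaves <- which(lengths(children) == 0L)
    v <- leaves[sample.int(length(leaves), 1)]
    id1 <- length(children) + 1L
    id2 <- id1 + 1L
    children[[id1]] <- integer(0)
    children[[id2]] <- integer(0)
    lab[id1] <- lab[v]
    lab[id2] <- labels[i]
    children[[v]] <- c(id1, id2)
    lab[v] <- NA_character_
  }
  new_gene_tree(children, lab, 1L)
}

#' Sample a random displayed tree of a network
#'
#' Chooses one incoming edge per reticulation uniformly at random and
#' returns the induced displayed tree as a gene tree.
#'
#' @param net a `phylo_network`
#' @param seed optional integer seed
#' @return a `displayed_tree`
#' @export
sample_displayed <- function(net, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  re <- net$retic_edges
  eids <- vapply(net$retic, function(r) {
    cand <- re$eid[re$head == r]
    cand[sample.int(length(cand), 1)]
  }, integer(1))
  display_tree(net, complete_perfect(net, eids))
}

#' Generate an R1/R2/R3-style dataset of (gene tree, network) pairs
#'
#' Every pair shares an n-leaf network with `r` reticulations; the gene tree
#' is, per style: R1 - an independent Yule-Harding tree on all n labels;
#' R2 - a Yule-Harding tree on a uniformly sized random label subset;
#' R3 - a randomly chosen tree displayed by the network.
#'
#' @param style `"R1"`, `"R2"` or `"R3"`
#' @param n network leaf count
#' @param r reticulation count
#' @param count number of pairs
#' @param seed integer seed (drives all randomness)
#' @param class network class passed to [add_reticulations()]
#' @return list of `list(gene, network, seed)` pairs
#' @export
make_dataset <- function(style = c("R1", "R2", "R3"), n, r, count,
                         seed = 1L, class = "treechild") {
  style <- match.arg(style)
  set.seed(seed)
  seeds <- sample.int(2147483646L, 3 * count)
  out <- vector("list", count)
  for (i in seq_len(count)) {
    s <- seeds[(3 * i - 2):(3 * i)]
    S <- sim_species_tree(n, s[1])
    net <- add_reticulations(S, r, s[2], class = class)
    G <- switch(style,
      R1 = sim_gene_tree(net_labels(net), s[3]),
      R2 = {
        set.seed(s[3])
        m <- sample(2:n, 1)
        sim_gene_tree(sample(net_labels(net), m))
      },
      R3 = sample_displayed(net, s[3]))
    out[[i]] <- list(gene = G, network = net, seed = s)
  }
  out
}

#' Write a dataset to paired Newick files plus a JSON manifest
#'
#' @param pairs result of [make_dataset()]
#' @param dir output directory (created if missing)
#' @param stem file-name stem
#' @return the manifest path, invisibly
#' @export
write_dataset <- function(pairs, dir, stem = "inst") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    gf <- file.path(dir, sprintf("%s%03d.gtree.nwk", stem, i))
    nf <- file.path(dir, sprintf("%s%03d.net.enwk", stem, i))
    writeLines(serialize_newick(pairs[[i]]$gene), gf)
    writeLines(serialize_newick(pairs[[i]]$network), nf)
    entries[[i]] <- list(gene = basename(gf), network = basename(nf),
                         seed = pairs[[i]]$seed)
  }
  mf <- file.path(dir, paste0(stem, ".manifest.json"))
  jsonlite::write_json(list(schema = 1L, entries = entries), mf,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(mf)
}
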