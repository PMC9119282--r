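# Shared fixtures: a one-reticulation tree-child network, a two-blob level-1
# network, a relaxed-but-not-tree-child network (reticulation above a
# reticulation), small gene trees, and seeded random instance helpers.

F1 <- "((a,(b)#H1)u,(#H1,c)v)r;"
F2a <- "((a,(b,c)),d);"
F2b <- "(a,d);"
F2s <- "((a,(b,c)),d);"
F3 <- "(((a,(b)#H1),(#H1,c)),((d,(e)#H2),(#H2,f)));"
F4 <- "((a,((b)#H2)#H1)u,(#H1,(#H2,c)w)v)r;"
F5 <- "((a,b),(b,c));"

net_f1 <- function() parse_enewick(F1)
net_f3 <- function() parse_enewick(F3)
net_f4 <- function() parse_enewick(F4)

# One random (gene tree, network) pair; r is capped so insertion stays
# feasible on small trees and the scenario space enumerable.
rand_pair <- function(seed, n = NULL, r = NULL, style = NULL,
                      class = "treechild") {
  set.seed(seed)
  n <- n %||% sample(5:9, 1)
  r <- r %||% sample(1:min(4, n - 2), 1)
  style <- style %||% sample(c("R1", "R2", "R3"), 1)
  tryCatch(
    c(make_dataset(style, n, r, 1, seed = seed, class = class)[[1]],
      list(style = style)),
    error = function(e) NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# named in-edge lookup: edge of `net` given leaf-ish node labels is awkward;
# fixtures use positional lookups via retic_edges() instead.
edge_by_tails <- function(net, lo = TRUE) {
  re <- retic_edges(net)
  re[order(re$tail, decreasing = !lo)[1], ]
}
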