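# The efficient DP: fixture traces, oracle equivalence, usage backtracking,
# conflicts, tie-breaks, and the DC-up variant.

test_that("dp_dc reproduces the fixture traces", {
  expect_equal(dp_dc(parse_gene_tree(F2a), parse_enewick(F2s))$score, 0L)

  net <- net_f1()
  r1 <- dp_dc(parse_gene_tree("(a,c);"), net)
  expect_equal(r1$score, 0L)
  expect_equal(nrow(r1$used), 2L)
  expect_length(usage_conflicts(r1$used, net), 1L)

  r2 <- dp_dc(parse_gene_tree("((a,b),c);"), net)
  expect_equal(r2$score, 0L)
  expect_length(usage_conflicts(r2$used, net), 0L)
})

test_that("dp_dup reproduces the fixture traces", {
  net <- net_f1()
  r1 <- dp_dup(parse_gene_tree("((a,b),c);"), net)
  expect_equal(r1$score, 0L)
  expect_equal(nrow(r1$used), 1L)
  expect_true(r1$used$direct[1])

  r2 <- dp_dup(parse_gene_tree("(a,c);"), net)
  expect_equal(r2$score, 0L)
  expect_equal(nrow(r2$used), 0L) # speciation through tree children

  expect_equal(dp_dup(parse_gene_tree(F2a), parse_enewick(F2s))$score, 0L)
})

test_that("DP equals both oracles on random instances and fixtures", {
  set.seed(51)
  done <- 0
  for (i in 1:40) {
    p <- rand_pair(1200 + i, n = sample(5:8, 1))
    if (is.null(p)) next
    U <- unfold_network(p$network)
    if (odtnet:::count_scenarios(p$gene, U) > 1500) next
    done <- done + 1
    dc_dp <- dp_dc(p$gene, p$network)$score
    expect_equal(dc_dp, best_scenario_bruteforce(p$gene, p$network,
                                                 "DC")$score)
    expect_equal(dc_dp, dc_score_cubic(p$gene, p$network))
    expect_equal(dp_dup(p$gene, p$network)$score,
                 best_scenario_bruteforce(p$gene, p$network, "DUP")$score)
  }
  expect_gte(done, 25)
  for (fx in c(F1, F3)) {
    net <- parse_enewick(fx)
    labs <- net_labels(net)
    set.seed(52)
    for (j in 1:3) {
      G <- sim_gene_tree(labs)
      expect_equal(dp_dc(G, net)$score,
                   best_scenario_bruteforce(G, net, "DC")$score)
    }
  }
  # relaxed fixture
  f4 <- net_f4()
  G <- parse_gene_tree("((a,b),c);")
  expect_equal(dp_dc(G, f4, mode = "relaxed")$score,
               best_scenario_bruteforce(G, f4, "DC")$score)
})

test_that("the backtracked used set is that of some optimal scenario", {
  set.seed(53)
  done <- 0
  key <- function(u) paste(sort(u$eid), collapse = ",")
  for (i in 1:12) {
    p <- rand_pair(1300 + i, n = 7, r = sample(2:3, 1))
    if (is.null(p)) next
    U <- unfold_network(p$network)
    if (odtnet:::count_scenarios(p$gene, U) > 1500) next
    done <- done + 1
    res <- dp_dc(p$gene, p$network)
    bf <- best_scenario_bruteforce(p$gene, p$network, "DC",
                                   keep_all_used = TRUE)
    expect_equal(res$score, bf$score)
    expect_true(key(res$used) %in%
                  vapply(bf$all_used, key, character(1)))
  }
  expect_gte(done, 6)
})

test_that("on reticulation-free networks the DP equals the tree costs", {
  set.seed(54)
  for (i in 1:8) {
    labs <- paste0("x", 1:sample(4:8, 1))
    S <- sim_gene_tree(labs)
    net <- parse_enewick(serialize_newick(S))
    G <- sim_gene_tree(sample(labs, sample(2:length(labs), 1)))
    expect_equal(dp_dc(G, net)$score, dc_cost(G, S))
    expect_equal(dp_dup(G, net)$score, dup_cost(G, S))
  }
})

test_that("dc_up_score equals the minimum rooted cost over displayed trees", {
  expect_equal(dc_up_score(parse_gene_tree("(b,c);"),
                           parse_enewick(F2s))$score, 2L)
  expect_equal(dc_up_score(parse_gene_tree(F2a),
                           parse_enewick(F2s))$score, 0L)
  expect_equal(dc_up_score(parse_gene_tree("(b,c);"), net_f1())$score, 1L)
  # like the plain DC score, the DC-up DP value is a lower bound on the
  # displayed-tree minimum, exact when the backtracked usage is conflict-free
  set.seed(55)
  for (i in 1:8) {
    p <- rand_pair(1400 + i, n = 7, r = 2, style = "R2")
    if (is.null(p)) next
    byhand <- min(vapply(displayed_trees(p$network), function(S)
      dc_up_cost(p$gene, S), integer(1)))
    res <- dc_up_score(p$gene, p$network)
    expect_lte(res$score, byhand)
    if (!length(usage_conflicts(res$used, p$network)))
      expect_equal(res$score, byhand)
  }
})

test_that("usage conflicts are reported per reticulation in id order", {
  net <- net_f1()
  re <- retic_edges(net)
  expect_length(usage_conflicts(re, net), 1L)
  expect_length(usage_conflicts(re[1, ], net), 0L)
  conf <- usage_conflicts(re, net)[[1]]
  expect_equal(nrow(conf), 2L)
  expect_equal(unique(conf$head), net$retic)
})

test_that("tie-breaks are deterministic and min-usage stays optimal", {
  set.seed(56)
  for (i in 1:6) {
    p <- rand_pair(1500 + i, n = 7, r = 3)
    if (is.null(p)) next
    a1 <- dp_dc(p$gene, p$network)
    a2 <- dp_dc(p$gene, p$network)
    expect_identical(a1$used$eid, a2$used$eid)
    m <- dp_dc(p$gene, p$network, tiebreak = "min-usage")
    expect_equal(m$score, a1$score)
    expect_lte(nrow(m$used), nrow(a1$used) + 2L) # sane, not explosive
  }
})

test_that("unmappable labels yield an infinite score and empty usage", {
  res <- dp_dc(parse_gene_tree("(a,z);"), net_f1())
  expect_true(is.infinite(res$score))
  expect_equal(nrow(res$used), 0L)
})

test_that("class violations are rejected per mode", {
  f4 <- net_f4()
  G <- parse_gene_tree("(a,c);")
  expect_error(dp_dc(G, f4, mode = "treechild"), class = "odt_class_error")
  expect_s3_class(dp_dc(G, f4, mode = "relaxed"), "odt_dp_result")
  n3 <- parse_enewick("(((a)#H1,(b)#H2)x,((#H1,#H2)y,c));")
  expect_error(dp_dc(G, n3), class = "odt_class_error") # two retic children
})
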