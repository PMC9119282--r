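# Unfolding, scenario enumeration and scoring, brute-force optimum, and the
# cubic first-formulation DP.

test_that("unfolding duplicates reticulation subtrees into a tree", {
  U1 <- unfold_network(net_f1())
  expect_equal(sort(U1$label[!is.na(U1$label)]), c("a", "b", "b", "c"))
  # every non-root node has one parent: it is a tree
  expect_true(all(!is.na(U1$parent[-U1$root])))

  Us <- unfold_network(parse_enewick(F2s))
  expect_equal(Us$orig, seq_along(Us$orig)) # identity on a tree

  U4 <- unfold_network(net_f4()) # nested reticulations: 3 copies of b
  expect_equal(sort(U4$label[!is.na(U4$label)]), c("a", "b", "b", "b", "c"))
})

test_that("root-leaf paths of N correspond one-to-one to unfolded leaves", {
  set.seed(41)
  for (i in 1:12) {
    p <- rand_pair(900 + i, class = sample(c("treechild", "relaxed"), 1))
    if (is.null(p)) next
    net <- p$network
    # count root-leaf paths in N by DP on the DAG
    paths <- numeric(net$n)
    paths[net$root] <- 1
    for (v in net$topo) for (w in net$children[[v]])
      paths[w] <- paths[w] + paths[v]
    leaves <- which(net$alive & net$outdeg == 0L)
    U <- unfold_network(net)
    expect_equal(sum(paths[leaves]), sum(!is.na(U$label)))
  }
})

test_that("scenario enumeration is the per-label Cartesian product", {
  net <- net_f1()
  U <- unfold_network(net)
  expect_length(enumerate_scenarios(parse_gene_tree("(a,c);"), U), 1)
  expect_length(enumerate_scenarios(parse_gene_tree("((a,b),c);"), U), 2)
  expect_error(enumerate_scenarios(parse_gene_tree("(a,z);"), U),
               "no copy")
})

test_that("scenario DC scores and used sets match hand traces on F1", {
  net <- net_f1()
  U <- unfold_network(net)
  G <- parse_gene_tree("(a,c);")
  xi <- enumerate_scenarios(G, U)[[1]]
  sc <- scenario_dc_score(G, U, xi)
  expect_equal(sc$score, 0L)
  used <- scenario_used(G, U, xi)
  expect_equal(nrow(used), 2L) # both siblings potentially used
  expect_true(all(used$potential))
  expect_true(attr(used, "conflict"))

  G2 <- parse_gene_tree("((a,b),c);")
  xis <- enumerate_scenarios(G2, U)
  scores <- vapply(xis, function(x) scenario_dc_score(G2, U, x)$score,
                   integer(1))
  expect_true(0L %in% scores)
  useds <- lapply(xis, function(x) scenario_used(G2, U, x))
  regular_opt <- mapply(function(s, u) s == 0L && !attr(u, "conflict"),
                        scores, useds)
  expect_true(any(regular_opt))
  u_reg <- useds[[which(regular_opt)[1]]]
  expect_equal(nrow(u_reg), 1L)
  expect_true(u_reg$direct[1])

  # single potentially-used edge need not be perfect
  Gc <- parse_gene_tree("(b,c);")
  xis_c <- enumerate_scenarios(Gc, U)
  any_single_pot <- any(vapply(xis_c, function(x) {
    u <- scenario_used(Gc, U, x)
    nrow(u) >= 1 && !attr(u, "conflict")
  }, logical(1)))
  expect_true(any_single_pot)
})

test_that("on a reticulation-free network the score equals the DC cost", {
  net <- parse_enewick(F2s)
  U <- unfold_network(net)
  G <- parse_gene_tree(F2a)
  xis <- enumerate_scenarios(G, U)
  expect_length(xis, 1)
  expect_equal(scenario_dc_score(G, U, xis[[1]])$score,
               dc_cost(G, parse_gene_tree(F2s)))
  expect_equal(scenario_dc_score(G, U, xis[[1]])$score, 0L)
})

test_that("scenario duplication scores match direct computation", {
  net <- net_f1()
  U <- unfold_network(net)
  G2 <- parse_gene_tree("((a,b),c);")
  scores <- vapply(enumerate_scenarios(G2, U), function(x)
    scenario_dup_score(G2, U, x), integer(1))
  expect_true(0L %in% scores)

  tiny <- parse_enewick("(a,b);")
  Ut <- unfold_network(tiny)
  Gd <- parse_gene_tree("((a,a),b);")
  expect_equal(scenario_dup_score(Gd, Ut,
                                  enumerate_scenarios(Gd, Ut)[[1]]), 1L)
})

test_that("brute force finds the optimum and the regularity certificate", {
  net <- net_f1()
  bf <- best_scenario_bruteforce(parse_gene_tree("(a,c);"), net, "DC")
  expect_equal(bf$score, 0L)
  expect_false(bf$regular_exists) # optimal displayed-tree cost is 1

  bf2 <- best_scenario_bruteforce(parse_gene_tree("((a,b),c);"), net, "DC")
  expect_equal(bf2$score, 0L)
  expect_true(bf2$regular_exists)

  bf3 <- best_scenario_bruteforce(parse_gene_tree(F2a),
                                  parse_enewick(F2s), "DC")
  expect_equal(bf3$score, 0L)
})

test_that("the cubic DP equals brute force on fixtures", {
  net <- net_f1()
  expect_equal(dc_score_cubic(parse_gene_tree("(a,c);"), net), 0L)
  expect_equal(dc_score_cubic(parse_gene_tree("((a,b),c);"), net), 0L)
  expect_equal(dc_score_cubic(parse_gene_tree(F2a), parse_enewick(F2s)), 0L)
})

test_that("a switching's tree cost equals its scenario score iff no edge
           of the switching is bypassed", {
  # The induced scenario's score lower-bounds the displayed-tree cost; the
  # gap is exactly the number of Type III visits that bypass an edge of Y
  # itself. Equality therefore holds iff the used set is contained in Y —
  # a strictly stronger condition than mere conflict-freeness.
  set.seed(44)
  done <- 0
  strict_regular <- 0
  for (i in 1:15) {
    p <- rand_pair(2100 + i, n = sample(5:9, 1),
                   style = sample(c("R1", "R2"), 1))
    if (is.null(p)) next
    U <- unfold_network(p$network)
    if (odtnet:::count_scenarios(p$gene, U) > 2048) next
    done <- done + 1
    for (Y in perfect_sets(p$network)) {
      xi <- scenario_from_perfect(p$gene, U, Y)
      sc <- scenario_dc_score(p$gene, U, xi)
      cost <- dc_cost(p$gene, display_tree(p$network, Y))
      used <- scenario_used(p$gene, U, xi)
      in_Y <- all(used$eid %in% Y$eid)
      no_bypass_of_Y <- !any(sc$bypassed %in% Y$eid)
      expect_identical(in_Y, no_bypass_of_Y)
      expect_identical(cost == sc$score, in_Y)
      expect_identical(cost - sc$score, sum(unlist(lapply(
        seq_len(p$gene$n), function(v) lapply(p$gene$children[[v]],
          function(w) {
            res <- odtnet:::walk_gene_edge(
              U, sc$m[v], sc$m[w])
            sum(res$bypassed %in% Y$eid)
          })))))
      if (in_Y) expect_false(attr(used, "conflict"))
      if (!attr(used, "conflict") && !in_Y) strict_regular <- strict_regular + 1
    }
  }
  expect_gte(done, 8)
})

test_that("perfect sets induce scenarios with a unique surviving copy", {
  set.seed(43)
  for (i in 1:6) {
    p <- rand_pair(1100 + i, n = 7, r = 3)
    if (is.null(p)) next
    U <- unfold_network(p$network)
    for (Y in perfect_sets(p$network)) {
      xi <- scenario_from_perfect(p$gene, U, Y)
      expect_true(all(xi[p$gene$is_leaf] > 0))
      expect_equal(U$label[xi[which(p$gene$is_leaf)]],
                   p$gene$label[which(p$gene$is_leaf)])
    }
  }
})
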