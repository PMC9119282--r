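# odtnet

Embedding gene trees into phylogenetic networks under the deep coalescence
and duplication costs.

## The problem

A rooted binary phylogenetic network *N* models reticulate evolution
(hybridization, recombination, horizontal transfer): reticulation nodes
have two parents, and choosing one incoming edge per reticulation (a
*switching*, or perfect set *Y*) collapses *N* to one of up to 2^r
*displayed trees* N_Y. Given a gene tree *G* (leaf labels may repeat —
MUL-trees are allowed), the **optimal displayed tree** (ODT) problem asks
for the displayed tree minimizing a reconciliation cost:

- **deep coalescence**: DC(G,S) = Σ_{⟨v,w⟩∈E(G)} (‖M(v),M(w)‖ − 1), the
  number of extra gene lineages under the lca-mapping M;
- **duplication**: DUP(G,S) = number of internal gene nodes mapping to the
  same species node as one of their children.

Enumerating all 2^r displayed trees is the standard but expensive route.
`odtnet` instead scores *scenarios* — label-preserving maps from gene
leaves into the unfolded network — with an O(|G||N|) dynamic program whose
value lower-bounds the ODT cost and whose backtracking reports the
reticulation edges the optimum uses. When that used set is *conflict-free*
(no reticulation contributes both parents) the bound is tight and a
witness displayed tree falls out; otherwise a conflict is resolved by
branching on its two edges (at most 2^{r+1}−1 DP calls, far fewer when
gene tree and network are congruent). The package targets *tree-child*
networks and the broader *relaxed* class (every node has at most one
reticulation child), adds a per-blob solver for level-k networks, a
depth-bounded branch-and-bound giving lower/upper cost bounds, exhaustive
small-scale oracles, and simulators for random networks and gene trees.

## Worked example

```r
library(odtnet)

net <- parse_enewick("((a,(b)#H1),(#H1,c));")  # one reticulation, H1
G   <- parse_gene_tree("(a,c);")

dp_dc(G, net)
#> DC scenario score: 0 (mode treechild)
#>   used reticulation edges: 2 (conflicted)

solve_odt(G, net, cost = "DC")
#> optimal displayed tree (DC, conflict-resolution): cost 1
#>   (a,(b,c));
#>   DP invocations: 3
```

The scenario score 0 is a strict lower bound here: the only scenario uses
both parents of H1 (a conflict), so no displayed tree attains 0. Branching
on the conflict solves the two pruned networks — the displayed trees
`((a,b),c)` and `(a,(b,c))` — and both cost 1, which is the exact ODT
cost. With `G = ((a,b),c)` the DP is conflict-free at once: cost 0 after a
single DP invocation, with witness tree `((a,b),c)`.

Bounds and the level-k and naive solvers work the same way:

```r
odt_bounds(G, net, maxdepth = 0, cost = "DC")   # [0, 1]
naive_odt(G, net, cost = "DC")$cost             # 1
```

A thin command-line wrapper ships as `inst/exec/odtnet` with verbs
`score`, `solve`, `bounds`, `levelk`, `naive`, `simulate`, `validate`,
emitting versioned JSON reports.

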