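---
title: "Optimal displayed trees by conflict resolution: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal displayed trees by conflict resolution: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odtnet)
```

## Model

A phylogenetic network here is a rooted binary DAG: tree nodes have one
parent and two children, reticulations two parents and one child, and
leaves are labeled one-to-one with species. A gene tree is rooted and
binary with possibly repeated labels (a MUL-tree). Deleting all but one
incoming edge per reticulation (a *perfect set*, or switching, `Y`) and
contracting the semi-binary remainder yields a *displayed tree* `N_Y`; in
the relaxed network class (at most one reticulation child per node, which
admits reticulations stacked on reticulations) the contraction must also
prune reticulations that lost their only child, which this package's
rewriting system does as one of its three confluent rules.

The costs are the classical reconciliation quantities under the
lca-mapping `M`: deep coalescence `DC(G,S) = sum over gene edges of
(||M(v),M(w)|| - 1)` (extra gene lineages), and duplication `DUP(G,S)` =
number of internal gene nodes mapping onto a child's image. The optimal
displayed tree (ODT) problem minimizes either cost over all trees
displayed by `N`.

## Scenarios and the dynamic program

Instead of enumerating switchings, the package scores *scenarios*:
label-preserving maps from gene leaves into the leaves of the *unfolded*
network (the tree of root-leaf paths of `N`). Each gene edge walks a path
in the unfolding; its visited edges classify into four types, of which
Type I (first edge) and Type II (ordinary descent) are charged, while
Type III (descent that bypasses a reticulation edge) and Type IV (the edge
below a reticulation) are free. The resulting score is a lower bound on
the ODT cost. A scenario *uses* a reticulation edge directly (a Type I/II
visit maps onto it) or potentially (its sibling is bypassed); a
reticulation with both incoming edges used is a *conflict*. A
conflict-free (regular) optimal scenario certifies that the bound is
tight, and completing its used set to a switching produces a witness
displayed tree.

One refinement matters when relating a *fixed* switching `Y` to the
scenario it induces: the displayed-tree cost exceeds that scenario's score
by exactly the number of Type III visits that bypass an edge of `Y`
itself, so the two agree iff the scenario's used set is contained in `Y`
(no `Y` edge bypassed). That containment implies conflict-freeness but
not conversely — a conflict-free induced scenario can still undercut its
own switching's cost — which is why exactness certificates here are
always phrased through the used set of an *optimal* scenario (a
conflict-free optimal used set extends to some perfect switching, whose
tree attains the bound), never through conflict-freeness of an arbitrary
switching's induced scenario.

The score is computed by a dynamic program over `V(G) x V(N)` with three
tables: `delta(g,s)` (image of `g` fixed at `s`), `deltaf` (`delta` plus
the cost of the edge entering `g`) and `deltaup` (image anywhere at or
below `s`), each cell O(1) given the network in reverse topological order
and the gene tree grouped by height, so the whole program is O(|G||N|)
and is evaluated as vectorized column sweeps. Reticulation columns exist
only for `deltaup`; the optimal score is `-|E(G)| + min over
non-reticulation s of delta(root, s)`. On a reticulation-free network the
score collapses to the ordinary tree-tree cost. The same table layout
with four speciation/duplication branch cases yields the duplication DP,
and reading `deltaup` at the network root gives the *rooted* variant
(DC-up) that the level-k solver charges to non-root blobs. Like the plain
score, the DC-up table value is a lower bound on the corresponding
displayed-tree minimum, exact when its backtracked usage is
conflict-free.

A single formulation covers both network classes: the reticulation case
of `deltaup` is written `tau(child) + deltaup(child)` (with `tau` zero on
reticulations), which equals the tree-child form because a reticulation's
child is never a reticulation there, and is the correct relaxed form
otherwise. General binary networks in which a tree node has two
reticulation children are rejected up front: the lower-bound property
fails there and the DP would silently undercount.

## Backtracking, tie-breaks and conflicts

Usage sets are reconstructed by the standard backtracking, adding the
descended-into reticulation edge (directly used) and, when the descent
bypasses a sibling reticulation edge, that sibling's sibling (potentially
used). Optimal cells frequently admit several argmin branches; the
package resolves ties *toward deeper mappings* (descend before stop,
children in node-id order). The alternative of stopping early is equally
optimal in score but tends to map gene nodes high in the network, where
both root edges bypass reticulations and manufacture conflicts; on the
running one-reticulation example it turns a conflict-free optimum into a
conflicted one. Preferring descent keeps usage sets conflict-free
whenever the gene tree actually is displayed by the network, which is
what makes the solver's branching rare on congruent data. An opt-in
`tiebreak = "min-usage"` instead compares the usage sets of all tying
branches and keeps the lexicographically smallest — a heuristic toward
minimizing conflicts that costs extra backtracking work and is off by
default.

## Solvers

`solve_odt` runs the DP; a conflict-free usage ends the recursion,
otherwise the first conflict (lowest reticulation id) is resolved by
solving the two networks with one conflict edge pruned each (`N_e` is the
network with `e` deleted and semi-binary nodes contracted; node and edge
ids are stable under pruning, so deep results lift back to the input
network's edge space, the pruned edge's sibling becoming mandatory). The
recursion performs at most `2^(r+1)-1` DP invocations but typically far
fewer. A `hybrid_threshold` switches to naive enumeration below a chosen
reticulation count, which pays off when `r` is small. `odt_bounds` is the
same recursion cut off at a depth: at a conflicted cutoff the DP score is
kept as the lower bound and the cost of the displayed tree obtained by
resolving every conflict toward the lower-tail edge (then completing) as
the upper bound; minima of both propagate upward, so the intervals nest
as the depth grows and collapse to the exact cost at unlimited depth.
`naive_odt` enumerates all switchings (deduplication by canonical form is
available separately via `displayed_trees`).

`solve_levelk` decomposes the network into blobs (nontrivial biconnected
components of the underlying undirected graph, via `igraph`); both ends
of every reticulation edge sit in one blob, so blobs can be switched
independently. Non-root blobs are processed bottom-up: the maximal gene
subtrees whose labels fit inside the blob's subnetwork are scored with
the rooted DC-up objective at the blob root (their entering edges are
charged through the path term), by conflict resolution restricted to the
blob; the final component containing the network root is solved with the
ordinary objective, producing the overall cost. On every tested input the
result equals `solve_odt`'s, with the per-blob invocation counts bounded
by the per-blob reticulation numbers.

One classical claim deserves a caveat: the two pruned networks of a
sibling pair partition the *multiset* of displayed trees, and that union
identity is what the recursion relies on; their sets of distinct
topologies, however, can overlap when a reticulation's two parents are
adjacent (a triangle — both switchings then collapse to the same tree),
so disjointness is not assumed anywhere.

## Oracles

Two independent ground-truth routes check the DP at small scale: (i)
explicit unfolding plus exhaustive scenario enumeration with per-edge
type traces (capped at 10^6 scenarios), which also certifies regularity
by inspecting every optimal scenario; and (ii) the cubic
first-formulation DP whose path-cost table walks the network explicitly.
The test suite demands exact agreement of all three on hundreds of random
instances, for both costs, and verifies the per-switching lower-bound and
regularity propositions by enumerating every perfect set.

## Simulated data

`sim_species_tree` draws Yule trees (uniform lineage splits, exponential
waiting times) normalized to unit height — only relative node times
matter, since reticulation insertion uses times solely through
uniform(parent, child) draws at subdivision points. `add_reticulations`
repeats the published insertion move: subdivide two random non-reticulation
edges, connect the lower-time vertex to the higher-time one, and reject
the move if the requested class is violated (budget 1000 attempts per
reticulation; dense small trees can exhaust it, which surfaces as an
explicit error rather than a silently easier instance). Time consistency
makes the result acyclic by construction and keeps every displayed tree
ultrametric. Gene trees come from the Yule–Harding model; the R1/R2/R3
designs pair a network with an independent gene tree on all labels (R1),
on a random label subset (R2), or with one of its own displayed trees
(R3). R3 is the congruent regime in which the solver rarely branches;
the acceptance suite checks that the mean of `log2(invocations)/r` stays
below 0.8 there and that duplication branches no more than deep
coalescence. These generators emulate topology and timing only — no
sequence evolution, estimation error or lineage sorting — so green tests
certify algorithmic correctness and scaling on clean topologies, not
robustness to gene-tree error.

Problem sizes used by the tests (leaves up to 14, reticulations up to 8,
hundreds of instances) keep the whole suite in the minutes range while
still exercising every branch of the recursion; the oracles cap scenario
spaces at a few thousand per instance.

## Numerical and degenerate-input choices

Infinity is a genuine `Inf` sentinel absorbing addition, never a large
finite number; unmappable gene labels therefore surface as an infinite
score with empty usage rather than an error in the DP (parsers and
solvers validate inputs separately, with typed error conditions mapped to
CLI exit codes 2/3/4). Canonical serialization orders children by
smallest descendant label with the expanded subtree form as tie-break,
prints each reticulation subtree at its first occurrence and numbers
`#H` tags in print order, making isomorphism checks string comparisons;
round-trip identity is asserted across random networks. Contraction is a
three-rule rewriting system run to a fixed point and tested for
confluence under randomized rule orders. A single-leaf gene tree has no
edges and scores 0 wherever its label occurs.

## Limitations

Unrooted gene trees, duplication-loss costs, non-binary inputs and
network inference are out of scope. Enumerative components (naive solver,
displayed-tree listing, oracles) are capped at r ≤ 16 / 10^6 scenarios.
The level-k solver currently targets the deep coalescence cost. The
empirical recombination case study that motivates the relaxed class needs
external sequence data and ML tree estimation; it ships only as a recipe
(`inst/extdata/coronavirus-replication-recipe.md`).
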