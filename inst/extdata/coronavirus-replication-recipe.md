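# Replication recipe: coronavirus recombination case study (out of scope)

The solvers in this package can score empirical gene trees against a
recombination network of betacoronaviruses, recovering which recombination
(reticulation) edges each gene's optimal deep-coalescence scenario uses.
That analysis is *not* reproduced by this package's tests or acceptance
script because it depends on external sequence retrieval and
maximum-likelihood gene-tree estimation. To repeat it:

1. Collect whole-genome sequences for a panel of SARS-CoV-2-related
   betacoronaviruses (human, bat and pangolin isolates) from GenBank/GISAID,
   restricted to species without multifurcations in the published species
   tree.
2. For each of the genes M, ORF1ab, ORF3a, ORF6, ORF8 and ORF10: align the
   per-gene sequences (e.g. MUSCLE), clean the alignment (e.g. GBlocks with
   relaxed settings), estimate an ML gene tree (e.g. RAxML, GTR+Gamma), and
   root it against the corresponding displayed tree.
3. Express the published species tree with its recombination events
   H1..H7 as extended Newick; where a transfer's direction is uncertain,
   build one network variant per direction (these networks are relaxed, not
   tree-child, so run the solvers with `mode = "relaxed"`).
4. For every (gene tree, network variant) pair run
   `solve_odt(G, N, cost = "DC", mode = "relaxed")` (or the `odtnet solve`
   CLI verb) and inspect the reported perfect set: a recombination edge is
   confirmed when the gene expected to cross it uses it in the optimal
   scenario.

Reported per-gene optimal displayed-tree costs in the original study of
this dataset were ORF3a: 0, ORF10: 5, ORF6: 1, M: 3, ORF8: 2, ORF1ab: 2;
these values are quoted for orientation only and are not recomputed here.
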