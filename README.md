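# ndtree: node-list phylogenetic trees with local updates

`ndtree` is an R package for researchers who manipulate rooted phylogenetic
trees — adding and removing tips, grafting missing taxa under taxonomic
constraints, simulating tree growth, and computing branch-length statistics
over communities of tips.

Most R phylogenetics code represents a tree as an edge matrix, which is
excellent for model-based statistics but awkward for manipulation: every tip
insertion renumbers the matrix and forces a whole-tree recompute. `ndtree`
instead stores a tree as a **dictionary of named node records**. Each record
for a node *n* carries:

- `id` — a unique, persistent name;
- `spn` — the span (length) of the edge immediately above *n*;
- `prid` — the full ancestor path of *n*, nearest parent first;
- `ptid` — the immediate children of *n*;
- `kids` — every tip descending from *n*;
- `pd` — the phylogenetic diversity of *n* (total span of all its
  descendants);
- `prdst` — the root-to-node distance (span included);
- an optional taxonym `txnym` and free-form user data.

Because each record carries its own context, inserting or deleting a tip
rewrites only the records on the insertion path and in the subtree below the
split edge — work proportional to local structure, not to tree size — and
per-node statistics become simple vectorised sweeps over the node list.
Node ages are derived on demand as `treeAge - prdst`, so they are never
stale.

The statistics built on this representation, in standard notation:

- **Fair Proportion evolutionary distinctness** of tip *t*:
  `FP(t) = Σ_e spn(e) / n_tips(e)` over the edges *e* on the path from *t*
  to the root (root excluded), where `n_tips(e)` is the number of tips below
  *e*. FP partitions total branch length: `Σ_t FP(t) = PD(tree)`.
- **Faith phylogenetic diversity** of a tip set: total span of the minimal
  subtree connecting the set (stem above its MRCA excluded).
- **Community overlap** (UniFrac-style, asymmetric): shared represented
  branch length of two tip sets divided by the first set's represented
  branch length, with a permutation test for phylogenetic turnover.
- **Patristic distance matrices**, **Robinson–Foulds distances** on shared
  tips, and the **Colless imbalance index**.
- An **evolutionary-distinctness-biased Markov model (EDBMM)** tree-growth
  simulator in which tips are born and die with selection weight
  `FP^(-edPower)`, nesting the equal-rates Markov model at `edPower = 0`.

## A worked example

```r
library(ndtree)
tr <- readNewick("((A:1,B:1)n1:1,C:2)root;")
tr
#> NodeTree (node-list phylogeny)
#> tips:   3
#> nodes:  5
#> root:   root
#> spans:  all nodes
#> pd:     5
#> age:    2
#> extant tolerance: 0
```

The tree has total branch length 5 and age 2 (the deepest root-to-tip
distance). Indexing by id shows one node record:

```r
tr[["n1"]]
#> node:     n1  (internal)
#> span:     1
#> parent:   root
#> children: A, B
#> kids:     2
#> pd:       2
#> prdst:    1
#> age:      1
```

Fair Proportion splits each edge's span evenly among its descendant tips: A
gets its own unit edge plus half of `n1`'s (1.5), C gets its whole 2-unit
edge, and the scores sum to the tree's total branch length:

```r
calcFrPrp(tr)
#>   A   B   C
#> 1.5 1.5 2.0
```

The overlap of community {A,B} with {B,C}: {A,B} represents edges A, B and
n1 (span 3), of which B and n1 (span 2) are shared, giving 2/3:

```r
calcOvrlp(tr, c("A", "B"), c("B", "C"))
#> [1] 0.6666667
```

Adding a tip splits one edge locally — here 4 node records were written
(two new nodes, the split edge, and the root's bookkeeping), not the whole
tree:

```r
resetTouchCount()
tr2 <- addTip(tr, "D", "C", strtAge = 2, endAge = 0, rngSeed = 1)
touchCount()
#> [1] 4
writeNewick(tr2)
#> [1] "((A:1,B:1)n1:1,(C:0.5310173262842,D:0.5310173262842)p1:1.4689826737158)root;"
```

A command-line interface covering tree summaries, statistics, pinning,
simulation and the turnover test is installed at
`system.file("scripts", "ndtree", package = "ndtree")`; see `?runCli`.

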