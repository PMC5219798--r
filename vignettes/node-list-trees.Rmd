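---
title: "Node-list trees: model, statistics and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Node-list trees: model, statistics and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ndtree)
```

## The data model

A `NodeTree` stores a rooted phylogeny as a named list of node records
rather than an edge matrix. Each record holds the node's id, the span of
its preceding edge, the ordered ancestor path to the root (`prid`, nearest
parent first), its immediate children (`ptid`), its descendant tip set
(`kids`), and — when every non-root node has a span — two precomputed
branch-length summaries: the per-node phylogenetic diversity `pd` (total
span of all descendants) and the root-to-node distance `prdst` (own span
included). Tips have an empty `ptid` and a non-empty `prid`; the root is
the unique node with an empty `prid`; internal nodes have both. Every id
referenced anywhere must resolve within the node list; `validateTree()`
audits all of these invariants plus the numeric fields against a fresh
recompute and returns a violation table rather than raising.

Two representation choices deserve comment:

- **The root's span.** A root has no preceding edge, so a span supplied for
  it (e.g. by a Newick root-edge length) is stored but excluded from the
  tree's total branch length, from per-node `pd`, and from Fair Proportion.
  It does enter `prdst` bookkeeping, keeping the record recursion uniform.
- **Ages are not stored.** A node's age is `treeAge - prdst`, computed on
  demand by `getNdAge()`. Materialising ages in the records would force any
  operation that changes the tree age (for example removing the oldest tip)
  to rewrite every record, destroying the locality property below. Ages
  decrease toward the tips: extant tips of an ultrametric tree sit at age
  0, and `setTol()` widens the band of tip ages that still count as
  "extant".

## Incremental updates and the locality contract

`addTip()`, `rmTip()` and `setNdSpn()` update the tree incrementally.
Inserting a tip on an edge rewrites exactly: the two new records, the split
edge's node and all nodes below it (their ancestor paths gain the new
internal node), and the nodes on the path from the insertion point to the
root (their `kids` and `pd` gain the new tip). `refreshDerived()` — a full
recompute of every derived field from child pointers and spans alone — is
the correctness oracle: after any operation the maintained tree must equal
its own full recompute, exactly for ids, topology and sets, and within an
absolute tolerance of 1e-9 for reals. The test suite enforces this over a
thousand random operation sequences.

Locality is made observable rather than asserted about wall-clock time: a
counter (`touchCount()`) records how many node records each incremental
operation wrote. Growing a fully balanced tree from 2 to 1,024 tips by
repeated terminus insertions, the per-insertion count grows like the
insertion depth (about `log2 n` plus a constant; 12 records at 1,024
tips), and the least-squares slope of `log(touched)` against `log(nTips)`
stays far below 0.5. The acceptance script recomputes this slope on every
run. When a removal leaves the root with a single child, the root absorbs
that child; the absorbed span lies on no tip-to-tip path, so the patristic
metric is unchanged, though the total branch length shrinks accordingly.

## Statistics

All statistics read the precomputed record fields directly.

- **Patristic distances.** `d(a, b) = prdst(a) + prdst(b) - 2 prdst(m)`
  with `m` the most recent common ancestor. The MRCA convention treats a
  node as its own ancestor. The test suite checks the matrix against an
  independent path-walking recount and against an external Newick reader's
  cophenetic matrix.
- **Fair Proportion.** Each edge's span is divided evenly among its
  descendant tips; a tip's score sums its shares along its root path (own
  edge included, root excluded). The implementation composes the record
  fields exactly: the ancestor path supplies the edges, the stored `kids`
  sets supply the divisors. Conservation — scores summing to total branch
  length — holds by construction and is asserted to 1e-9 on random trees.
- **Phylogenetic diversity.** Sum of spans over the minimal subtree
  connecting a tip set, excluding the stem above the set's MRCA. The stem
  exclusion is a deliberate choice: it makes the diversity of the full tip
  set equal the tree's total branch length, which in turn anchors the
  whole-tree identity used in testing.
- **Community overlap.** A community represents every non-root node on a
  path from one of its tips to the root. The reported overlap is the
  shared represented span divided by the *first* community's represented
  span — an asymmetric quantity ("how much of red's branch length does
  blue also cover"); `norm = "union"` switches to the symmetric
  shared-over-union variant for users who want a distance-like measure.
- **Tree distance.** Robinson–Foulds on the shared-tip restriction: each
  internal node induces a bipartition of the shared tips, trivial splits
  are dropped, and the distance counts splits present in exactly one tree.
  This is the conventional reading for a topology-comparison utility; an
  independent implementation (`phangorn::RF.dist`) serves as the
  cross-check in the tests, never as the implementation.

## Taxonomically constrained pinning

`pinTips()` grafts candidate tips whose phylogenetic position is known only
through a taxonomic lineage. For each candidate the lineage is walked from
its most specific name toward the root; the first name carried by any
node's taxonym fixes the host clade. Among several nodes carrying the name
the one with the most descendant tips wins, ties broken by id order — one
clade per taxonym is the expected case, and the rule is deterministic when
it is not. The attachment edge is drawn uniformly from the host clade's
edges, the clade's own stem included (placement at the stem says "inside
this taxon but sister to everything sampled"), subject to the edge being
old enough to accommodate the new tip's age; the attachment point on that
edge is then drawn uniformly over the admissible age interval. Candidates
are processed in input order and each pinned tip adopts the most specific
name of its lineage as its own taxonym, so earlier pins can host later
ones. Candidates matching no taxonym are skipped and reported in the
`pinReport` attribute, never fatal. `taxonomiseTree()` provides the
synthetic taxonomy used in simulation studies: every internal node is
labelled from its id, which makes "the clade of the most specific matched
name" unambiguous and lets the tests audit every placement.

## Tree-growth simulation

`simulateEDBMM()` grows a tree in discrete iterations. Per iteration, in
order: Fair Proportion is computed for all extant tips; with probability
`birthProb` one tip is chosen with weight `FP^(-edPower)` and a new tip is
attached at its terminus with both daughter spans zero; with probability
`deathProb` a tip is chosen from the same weights and removed; finally
every extant tip's span is extended by `timeStep`. The zero-length daughter
edges plus the extension step make the iteration counter the clock, so
surviving lineages stay ultrametric while extinct lineages freeze in place
(an option prunes them at the end). At most one birth and one death occur
per iteration, with constant per-iteration probabilities rather than
per-lineage rates — a scripted-loop model, not a Gillespie simulation.

The bias functional `FP^(-edPower)` is this package's definition: it gives
a one-parameter family in which evolutionarily distinct tips speciate and
go extinct at lower rates for any `edPower > 0`, and which nests the
equal-rates Markov model exactly at `edPower = 0`. The weights are guarded
as `(FP + 1e-12)^(-edPower)` because a tip born in the current epoch can
have an arbitrarily small score; the guard is far below any meaningful FP
scale. Two behavioural anchors are tested rather than assumed: at
`edPower = 0` with pure birth the shape distribution must match the
constant-rate pure-birth generator (`randYuleTree()`) — mean Colless
imbalance within three standard errors of both the matched simulation and
the exact expectation from the uniform root-split recursion — and at
`edPower = 1` the imbalance distribution must shift detectably (it shifts
toward *more* imbalance: low-distinctness tips sit in bushy clades, so the
bias makes rich clades richer). The simulator halts with a recorded reason
if the tip count would fall below three or the extant fringe empties,
returning the partial tree and its event log.

## Turnover permutation test

`genCommunities()` draws two disjoint communities: a uniform seed tip each,
then members without replacement with weight `(d(t, seed) + 1e-6)^(-psi)`.
At `psi = 0` this is uniform sampling; increasing `psi` concentrates each
community around its seed. The generator's defaults are the study
conditions used throughout the tests: communities of 20 tips on 100-tip
pure-birth trees, 99 permutations, 200 replicates.

`permTestOvrlp()` fixes the first community and resamples the second
uniformly from the remaining tips — matching the generation constraint of
disjoint membership — and reports a one-tailed p-value in the low-overlap
(turnover) direction with the standard +1 rank correction, so p is never
zero and never exceeds one. Overlapping input communities are an error, not
silently tolerated. Under `psi = 0` the test is its own null, and its
type-I error at the 5% level calibrates into [0.02, 0.10] over 200
replicates; power is non-decreasing over `psi` in {0, 1, 2}. Both
properties are recomputed by the acceptance script.

## Newick input and output

The reader accepts standard single-tree Newick with branch lengths,
internal labels and quoted labels. Internal labels are node ids by default
(a flag demotes them to user data); unlabelled internal nodes receive
deterministic preorder auto-ids `n1, n2, ...`, skipping collisions with
existing labels. Malformed input is reported with a character offset.
The writer emits children in stored order and prints each span with the
shortest decimal representation that round-trips the double exactly, so
write-then-read reproduces topology, ids and spans without loss; 200
random trees are round-tripped in the acceptance checks. Trees without
spans read and write cleanly with all span-dependent operations disabled.
NEXUS, multi-tree files and unrooted trees are out of scope.

## What the synthetic generators do and do not emulate

`randYuleTree()` produces constant-rate pure-birth ultrametric trees —
the standard null for tree shape, with exponential waiting times and
uniform lineage choice. `balancedTree()` gives the fully symmetric
ultrametric extreme used for locality measurements. `taxonomiseTree()`
produces a perfectly consistent, fully resolved taxonomy. Real data differ
in known ways: empirical trees carry sampling artefacts, polytomies, and
non-ultrametric tips; real taxonomies are incomplete, partially
inconsistent with the phylogeny, and non-unique at many ranks. Passing
tests therefore demonstrate correctness of the algorithms under clean
conditions, not robustness to noisy taxonomies or to trees whose
calibration is itself uncertain. Polytomies are supported by the data
model and by every statistic except the Colless index, which rejects them
by definition.

## Numerical choices and problem sizes

Real-valued comparisons use an absolute tolerance of 1e-9 throughout; ids
are case-sensitive; a tree always has at least two tips, and operations
that would drop below that are errors. Degenerate age intervals in
`addTip()` resolve deterministically to the single admissible point. All
stochastic functions take an explicit seed, and the command-line interface
refuses to run stochastic commands without one. The standard problem sizes
used by the tests and the acceptance script — 100-tip trees for the
operation-sequence oracle, 1,024 tips for locality, 64 tips and 200
replicates for simulator shape comparisons, 200 replicates of 99
permutations for the turnover calibration, and a 256-tip tree with 50
candidates over 20 seeds for pinning — were chosen so each property has
comfortable statistical resolution while the whole suite remains quick to
run on a laptop.
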