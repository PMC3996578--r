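---
title: "Detecting all full subtree repeats: model, conventions and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting all full subtree repeats: model, conventions and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treerepeats)
```

## Problem and model

The input is an unrooted, unordered, labelled tree `T = (V, E)`:
`|E| = |V| - 1`, connected, every node carrying a symbol from a finite
alphabet, symbols freely repeating. A *full subtree* `T(v,u)` is the
component containing `v` after removing the single edge `{v,u}`; `T̂(v)`
denotes the whole tree rooted at `v`. Two rooted trees are *equal* when some
bijection of their node sets preserves adjacency and labels; child order
never matters in the unordered setting. A *repeat* is a maximal set of
pairwise-equal full subtrees. Repeats split into three kinds:
*non-overlapping* (members pairwise node-disjoint), *overlapping* (some node
common to all members) and *total* (every member is a whole-tree rooting).
The package computes all three, each class with its member `(root,
removed-neighbour)` tuples.

The decomposition into two stages is forced by a simple observation: a
repeat's members all have the same height, and disjoint equal subtrees can
only hang *below* the tree centre level (their height is at most half the
diameter), while equal subtrees that look *upward* must all contain the
centre and therefore overlap. So a bottom-up pass over the centre-rooted
tree finds exactly the non-overlapping classes, and a top-down pass over the
resulting identifiers finds exactly the overlapping and total ones.

## Rooting conventions

`build_rooted_view()` roots the tree at its centre, computed by iterative
leaf stripping. A bicentral tree gets a *virtual root* (sentinel id `n + 1`)
above its two adjacent centres; the edge between the centres is not
traversed downward. The virtual root carries no label, is excluded from the
height partition, and never appears in any reported member tuple: when the
two centres carry equal forward identifiers, the backward stage reports the
total repeat of the two whole-tree rootings but no overlapping class, since
the would-be shared parent is not a real node. Sizes 1 and 2 are the
degenerate central and bicentral cases and are handled explicitly.

Two conventions are deliberate choices rather than mathematical necessities,
and both only affect the *numbering* of classes, never the partition:

* **Queue order.** Height queues, children lists and per-set child scans all
  use ascending node id. Any fixed order would do; ascending id makes every
  trace reproducible. One consequence is worth writing down: at the topmost
  level of a bicentral tree the two centres are processed in ascending-id
  order, so the two top classes receive their identifiers in that order. A
  worked trace that happens to list the higher-id centre first will agree
  with this package's trace on every string, and on every class *set*, while
  swapping the two final identifier values — no traversal discipline can
  list the lower-id centre last at the top level yet first at every level
  below, so a single global convention has to pick one order; this package
  picks ascending everywhere.
* **Label numbering.** Label identifiers are assigned by first occurrence
  scanning nodes in ascending id order. Alphabetical numbering would be
  equally valid; first occurrence extends naturally to arbitrary (non-sortable,
  multi-character) label sets.

## The forward stage, step by step

For each height level, four lists are built (all exposed via
`trace_table()` and the per-level `level_trace` objects):

* `S` — one integer string per node: label identifier, then the class
  identifiers of the node's children. Label identifiers occupy `1..|Σ|` and
  class identifiers start at `|Σ| + 1`, so the label position is recoverable
  from the values alone; whole strings can therefore be compared as
  multisets without a separator.
* `R` — `S` with identifiers remapped to `1..m` by first occurrence. The
  remap uses one scratch array of length `|T| + |Σ|` allocated once per run;
  the cells touched at a level are remembered in a queue and reset
  afterwards, which keeps each level linear in its total string length
  without re-zeroing the array.
* `R'` — each string sorted internally, by bucket sort over `1..m`:
  every (identifier, string) tuple is dropped into its identifier's bucket
  and the buckets are swept in order, appending first-read-first-placed.
* `R''` — the strings of `R'` sorted lexicographically by a stable MSD radix
  sort on integer sequences; a shorter string precedes every extension.
  Maximal runs of equal adjacent strings are the classes; they receive
  consecutive identifiers in run order.

Sorting primitives are hand-written in the package rather than delegated to
`order()` precisely because the linear-time argument runs through them; the
brute-force oracle, where asymptotics are irrelevant, uses ordinary sorting.

## The backward stage

The recursion processes a queue of node sets, starting from the root. For a
dequeued set `U`, the forward identifiers of all children of members of `U`
are remapped densely and bucket-sorted; the resulting identifier groups are
sibling/child repeats. The emission rule is exactly the sufficiency
direction of the sibling/child-repeat correspondence: a group `{u_1,…,u_k}`
with `k ≥ 2` yields the total class `{(u_i,u_i)}` and the overlapping class
`{(parent(u_i), u_i)}`. Necessity guarantees nothing is missed, and —
because each node belongs to exactly one group — classes discovered from
different groups are never merged. Singleton groups emit nothing but are
still enqueued, so the recursion continues below non-repeating nodes
(`emit_singletons = TRUE` surfaces them for debugging). Groups are formed
jointly across all parents in `U`, which is what makes child repeats with
different parents land in one class.

Two checkable corollaries are implemented as predicates used by the test
suite rather than as optimizations: the *trivial path* property (every node
from the root of a frequency-1 class up to the nearest centre also roots a
frequency-1 class; `trivial_path_nodes()`) and its inclusion counterpart
(every member of every overlapping repeat of frequency above 1 contains all
trivial-path nodes).

## Variants

* **Rooted** (`run_rooted()`): only non-overlapping repeats exist, so the
  forward stage runs alone, looping over all height levels `0..h(root)`.
* **Ordered** (`run_ordered()`): the within-string bucket sort is skipped and
  children keep their input adjacency order, so equality requires matching
  ordered child sequences. The ordered partition always refines the
  unordered one. No ordered backward stage is provided; the scan object's
  backward field is `NULL` outside unrooted mode.
* **Unlabelled** (`run_unlabelled()`): all labels are replaced by the single
  uniform symbol `*`; the partition then reflects topology only and is
  always a coarsening of any labelled partition on the same topology.
* **Forest** (`run_forest()`): the roots of all member trees are attached to
  one virtual root and the forward stage runs on the combined object, so
  classes span trees. This is also the route to phylogenetic applications
  such as finding maximal equal subtrees across per-site trees: running the
  forest scan and taking the classes whose members are maximal under
  containment answers the leaf-agreement subtree question directly.

## Input handling

Newick reading goes through `ape::read.tree`, with two wrinkles worth
documenting. Node ids `1..n` are assigned by a pre-order walk of the parsed
tree (root first, children in input order) — the order nodes are first
encountered in the string — and are exposed in all outputs. Comma-free
strings (a single node, or a chain of nested unifurcations with one leaf)
are parsed directly, because one-tip trees are outside `ape`'s contract.
Parenthesis balance is pre-checked so syntax errors can name a character
position. The edge-list format (edges, blank line, `id label` table) takes
ids verbatim and is the way to pin node numbering down exactly — the shipped
28-node example uses it so that every trace row is bit-reproducible.

## The generators, and what they do not emulate

`random_tree(n, k, seed)` uses uniform random attachment (node `i` picks its
neighbour uniformly among `1..i-1`) with i.i.d. uniform labels. This
produces shallow, unbalanced trees with many small repeated subtrees near
the leaves — a good stress regime for class bookkeeping, but *not* a model
of phylogenies: no bifurcating structure, no labels-only-at-tips, and no
uniform sampling over isomorphism classes. Conclusions from passing tests
are about algorithmic correctness on arbitrary labelled trees, not about
statistical behaviour on real data.

`planted_repeat_tree(motif_size, copies, filler_size, seed)` grafts
`copies` disjoint copies of one random motif onto random nodes of a backbone
whose alphabet (upper case) is disjoint from the motif's (lower case). Two
facts make the recovery guarantee exact: label-disjointness means any
subtree equal to a motif copy must consist of motif-labelled nodes only, so
only the planted roots qualify; and the tree centre always lies in the
backbone (all copies have equal height, so the midpoint of any diameter path
sits at or above an attachment point), so each planted root's *downward*
subtree is exactly its motif copy. Hence the planted class has frequency
exactly `copies`.

## Numerical and degenerate-input choices

There is no floating point anywhere; determinism is exact. Identifiers are
dense integers, strings are integer vectors (never concatenated characters,
so multi-digit identifiers cannot collide), and the canonical-form oracle
brackets labels with explicit delimiters for the same reason. Ties in the
lexicographic sort are impossible between distinct strings; equal strings
keep input order (stability), which fixes class numbering. Degenerate
inputs — one node, two nodes, stars, pure paths, single-tip chains — are
covered by explicit tests.

## Verification strategy and problem sizes

The package carries its own independent oracle: `canonical_form()` is an
AHU-style recursive encoding with memoized directed-edge encodings, and
`bruteforce_repeats()` groups downward subtrees, upward subtrees and
whole-tree rootings by encoding. The test suite checks, per generated tree,
that forward classes equal the downward grouping and that backward
total/overlapping classes equal the rooting/upward groupings of size ≥ 2 —
member-for-member. The shipped checks run 500 random trees with `n` up to
200 and alphabets up to 5 symbols, plus 30 planted-repeat configurations and
20 property-suite trees; linearity is checked by elementary-operation
counters (string symbols touched, buckets swept, nodes enqueued) comparing
`n` against `2n` at `n = 100` and `250` — counters, not wall-clock, are the
measured surface. These sizes were chosen so the whole suite documents the
behaviour at meaningfully larger-than-toy scale while staying quick to run.

## Known limitations

* Only *full* subtrees are considered; partial-subtree repeats are a
  different (harder) problem.
* The backward stage reports upward/total repeats found through the
  sibling/child recursion; a hypothetical class mixing one downward and one
  upward subtree (necessarily disjoint, hence non-overlapping) is reported
  through the two stages separately, not merged — the two stages' oracle
  comparisons are scoped accordingly.
* Branch lengths, support values and NEXUS/phyloXML inputs are out of
  scope; labels are the only node attribute consumed.
* The asymptotic claims are backed by operation counting on the R
  implementation's data structures, not by micro-benchmarks; R-level
  constant factors are what they are.
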