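# treerepeats

Find **all repeated full subtrees** of an unrooted, unordered, labelled tree
and group them into equivalence classes — in time linear in the size of the
tree.

Phylogenetic inference returns unrooted unordered labelled trees, and
likelihood evaluation on such trees spends most of its time recomputing
identical conditional-likelihood entries for structurally identical subtrees.
Knowing every class of equal subtrees — across one tree, or across a forest
of per-site trees — lets that work be shared; the same primitive shows up in
common-subexpression elimination, term indexing and frequent-subtree mining.
`treerepeats` is for anyone who needs that equivalence structure explicitly:
which subtrees are equal, where they sit, and how often they repeat.

## The method

A *full subtree* `T(v,u)` is the component containing `v` after deleting the
single edge `{v,u}`. Two subtrees are *equal* when a bijection between their
nodes preserves both adjacency and labels (child order is irrelevant). A set
of pairwise-equal subtrees is a *repeat*; it is *non-overlapping* when the
member trees are pairwise node-disjoint, *overlapping* when some node lies in
all of them, and *total* when every member spans the whole tree (a repeat of
rootings).

The algorithm runs in two stages over the tree rooted at its centre (with a
virtual root above the two centres of a bicentral tree):

1. **Forward stage** (non-overlapping repeats). Nodes are processed bottom-up
   by height. Each node `v` becomes an integer string: the identifier of its
   label followed by the class identifiers of its children. Per level, the
   identifiers are remapped to a dense range `1..m` by first occurrence
   (scratch array + cleanup queue), sorted within each string by bucket sort,
   and the strings are sorted lexicographically by radix sort. Maximal runs of
   equal strings are the level's equivalence classes; each class gets a fresh
   identifier, assigned to its root nodes. Every step is linear, so the stage
   runs in `O(|T|)` overall.
2. **Backward stage** (overlapping and total repeats). A queue of node sets
   starts at the root. For each dequeued set, the forward identifiers of all
   children are bucket-sorted; each group of children sharing an identifier is
   a *sibling/child repeat* and is enqueued. A group `{u_1,…,u_k}`, `k ≥ 2`,
   certifies that the whole-tree rootings at the `u_i` are a total repeat and
   that the trees `T(parent(u_i), u_i)` are an overlapping repeat — and these
   conditions are also necessary, so the groups are exactly the classes. Each
   node is enqueued once: `O(|T|)` again.

Mode switches reuse the same machinery for rooted trees (forward stage over
all height levels of the chosen root), ordered trees (within-string sorting
omitted), unlabelled trees (one uniform symbol) and forests of rooted trees
(all roots joined under one virtual root, so classes span trees).

Everything is independently checkable: an AHU-style canonical-form oracle
(`canonical_form()`, `bruteforce_repeats()`) recomputes all classes by brute
force, and seeded generators (`random_tree()`, `planted_repeat_tree()`)
provide arbitrary test inputs.

## Worked example

The package ships a 28-node example tree over the alphabet `{a,b,c,d}`
(`fixture_tree()`, also in `inst/extdata/` as Newick and edge-list):

```r
library(treerepeats)
library(dplyr)

scan <- subtree_repeats(fixture_tree())
scan
#> <repeat_scan> 28 nodes (unrooted mode)
#>   classes: non-overlapping 11, overlapping 9, total 9
#>   with frequency >= 2: 26

glance(scan)
#> # A tibble: 1 × 9
#>       n sigma diameter n_centres non_overlapping non_overlapping_rep overlapping total forward_ops
#>   <int> <int>    <int>     <int>           <int>               <int>       <int> <int>       <int>
#> 1    28     4        7         2              11                   8           9     9         283
```

The tree is bicentral (centres 1 and 16, diameter 7). The forward stage
assigns label identifiers `a:1 b:2 c:3 d:4` and then, level by level, class
identifiers `5..15`; the two large subtrees hanging below the centre — rooted
at nodes 2 and 9 — end up in one class:

```r
scan$forward$node_class[c(2, 9)]
#> [1] 12 12
```

`trace_table(scan$forward)` exposes the per-level `S`/`R`/`R'`/`R''` lists
(strings, dense remap, within-string sort, lexicographic sort), e.g. at
height 1 the strings `3 6 7 5,3 5 7 6,2 5 7,1 8,2 5 7,1 8` remap to
`1 2 3 4,1 4 3 2,5 4 3,6 7,5 4 3,6 7`.

The backward stage turns matching sibling identifiers into overlapping and
total repeats; among them the frequency-2 overlapping class whose members are
the tree rooted at node 2 with the edge to node 4 removed, and its partner at
(9, 12):

```r
scan$backward$classes |>
  filter(kind == "overlapping") |>
  slice(3) |>
  pull(members)
#> [[1]]
#> # A tibble: 2 × 2
#>    root neighbour
#>   <int>     <int>
#> 1     2         4
#> 2     9        12
```

`tidy(scan, singletons = FALSE)` returns all 26 repeating classes as a
tibble; `write_repeats(scan$classes, "tsv")` (or `"json"`) serializes them
deterministically; `autoplot(scan)` draws the frequency spectrum per kind.

A thin command-line front end is installed under
`system.file("exec", "treerepeats", package = "treerepeats")` with
subcommands `repeats`, `forward`, `trace` and `generate`.

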