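Package: treerepeats
Title: Linear-Time Detection of Repeated Subtrees in Labelled Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Groups all full subtree repeats of an unrooted unordered labelled
    tree into equivalence classes in linear time. A forward, bottom-up stage
    detects all non-overlapping repeats by remapping, bucket-sorting and
    radix-sorting per-height identifier strings; a backward, top-down stage
    derives all overlapping and total repeats from the forward identifiers via
    sibling- and child-repeat recursion. Variants for rooted, ordered and
    unlabelled trees and for forests of rooted trees are included, together
    with a brute-force canonical-form oracle, seeded random-tree and
    planted-repeat generators, and tidy (tibble) accessors for all results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
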