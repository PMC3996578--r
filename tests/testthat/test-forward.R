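fixture_forward <- function() {
  run_forward(build_rooted_view(fixture_tree()))
}

test_that("label identifiers follow first occurrence in ascending id order", {
  expect_equal(assign_label_identifiers(fixture_tree()),
               c(a = 1L, b = 2L, c = 3L, d = 4L))
  expect_equal(assign_label_identifiers(path_tree(c("z", "k", "z"))),
               c(z = 1L, k = 2L))
  expect_equal(assign_label_identifiers(path_tree(c("q", "q"))), c(q = 1L))
})

test_that("level strings, remapping and sorting reproduce the worked example", {
  fw <- fixture_forward()
  tb <- trace_table(fw)
  row <- function(h, step) tb$value[tb$height == h & tb$step == step]
  expect_equal(row(0, "S"),  "2,1,3,2,4,4,2,2,3,1,1,2,3,4,2,3,4")
  expect_equal(row(0, "R"),  "1,2,3,1,4,4,1,1,3,2,2,1,3,4,1,3,4")
  expect_equal(row(0, "R'"), "1,2,3,1,4,4,1,1,3,2,2,1,3,4,1,3,4")
  expect_equal(row(1, "S"),  "3 6 7 5,3 5 7 6,2 5 7,1 8,2 5 7,1 8")
  expect_equal(row(1, "R"),  "1 2 3 4,1 4 3 2,5 4 3,6 7,5 4 3,6 7")
  expect_equal(row(1, "R'"), "1 2 3 4,1 2 3 4,3 4 5,6 7,3 4 5,6 7")
  expect_equal(row(1, "R''"), "1 2 3 4,1 2 3 4,3 4 5,3 4 5,6 7,6 7")
  expect_equal(row(2, "S"),  "1 5 9 8,1 8 5 9,1 11 10 11")
  expect_equal(row(2, "R"),  "1 2 3 4,1 4 2 3,1 5 6 5")
  expect_equal(row(2, "R'"), "1 2 3 4,1 2 3 4,1 5 5 6")
  expect_equal(row(2, "R''"), "1 2 3 4,1 2 3 4,1 5 5 6")
  # top level under the package's ascending-queue convention; as a multiset
  # of per-node strings this equals the published pair {"1 12 12","2 6 10 13"}
  expect_setequal(strsplit(row(3, "S"), ",")[[1]], c("1 12 12", "2 6 10 13"))
  expect_equal(row(3, "S"), "1 12 12,2 6 10 13")
  expect_equal(row(3, "R"), "1 2 2,3 4 5 6")
})

test_that("forward classes on the fixture match the hand-executed map", {
  fw <- fixture_forward()
  nc <- fw$node_class
  expect_equal(nc[c(3, 5, 6, 8)], c(5L, 6L, 7L, 8L))  # leaf classes b,a,c,d
  expect_equal(nc[c(4, 12)], c(9L, 9L))
  expect_equal(nc[c(18, 24)], c(10L, 10L))
  expect_equal(nc[c(22, 27)], c(11L, 11L))
  expect_equal(nc[c(2, 9)], c(12L, 12L))
  expect_equal(nc[21], 13L)
  expect_setequal(nc[c(1, 16)], c(14L, 15L))
  # identifiers are consecutive after |Sigma| and unique per class
  expect_equal(sort(unique(nc)), 5:15)
  # members carry (root, parent) tuples
  cls12 <- fw$classes[fw$classes$class_id == 12L, ]
  expect_equal(cls12$members[[1]]$root, c(2L, 9L))
  expect_equal(cls12$members[[1]]$neighbour, c(1L, 1L))
})

test_that("identifier remapping is dense, first-occurrence, and cleans up", {
  tr <- structure(list(level = 0L, nodes = 1:3,
                       S = list(c(7L, 9L), c(9L, 2L), c(7L, 7L))),
                  class = "level_trace")
  out <- remap_identifiers(tr)
  expect_equal(out$R, list(c(1L, 2L), c(2L, 3L), c(1L, 1L)))
  expect_equal(out$m, 3L)
  # already-dense input is untouched
  tr2 <- structure(list(level = 0L, nodes = 1:1, S = list(c(1L, 2L, 1L))),
                   class = "level_trace")
  expect_equal(remap_identifiers(tr2)$R, list(c(1L, 2L, 1L)))
  # a shared scratch array must give identical answers level after level
  scratch <- treerepeats:::new_scratch(16L)
  r1 <- remap_identifiers(tr, scratch)
  r2 <- remap_identifiers(tr, scratch)
  expect_identical(r1$R, r2$R)
})

test_that("within-string bucket sort and lexicographic radix sort behave", {
  tr <- structure(list(level = 1L, nodes = 1:3, m = 7L,
                       R = list(c(1L, 4L, 3L, 2L), c(6L, 7L), c(5L, 4L, 3L))),
                  class = "level_trace")
  out <- sort_within_strings(tr)
  expect_equal(out$R_sorted, list(c(1L, 2L, 3L, 4L), c(6L, 7L), c(3L, 4L, 5L)))
  lex <- lexsort_strings(out)
  expect_equal(lex$R_lex, list(c(1L, 2L, 3L, 4L), c(3L, 4L, 5L), c(6L, 7L)))
  # shorter string precedes its extension; stability keeps input order on ties
  tr2 <- structure(list(level = 0L, nodes = 1:4,
                        R_sorted = list(c(2L, 3L), 2L, c(2L, 3L), c(2L, 3L, 1L))),
                   class = "level_trace")
  lex2 <- lexsort_strings(tr2)
  expect_equal(lex2$lex_order, c(2L, 1L, 3L, 4L))
})

test_that("class frequencies sum to the level sizes and to n", {
  for (s in 1:10) {
    t <- random_tree(sample.int(150, 1), sample.int(5, 1), seed = 200 + s)
    v <- build_rooted_view(t)
    fw <- run_forward(v)
    per_level <- tapply(fw$classes$frequency, fw$classes$height, sum)
    H <- partition_by_height(v)
    expect_equal(as.integer(per_level), lengths(H))
    expect_equal(sum(fw$classes$frequency), t$n)
    # every node in exactly one class
    expect_true(all(!is.na(fw$node_class)))
    all_roots <- sort(unlist(lapply(fw$classes$members, `[[`, "root")))
    expect_equal(all_roots, seq_len(t$n))
  }
})

test_that("the class partition is invariant to node renumbering and label renaming", {
  for (s in 1:6) {
    t <- random_tree(sample.int(80, 1) + 1L, 3L, seed = 300 + s)
    v <- build_rooted_view(t)
    part <- root_partition(run_forward(v)$classes$members)
    # permute node ids: the partition must map through the permutation
    perm <- sample(t$n)
    tp <- permute_ids(t, perm)
    partp <- root_partition(run_forward(build_rooted_view(tp))$classes$members)
    remapped <- sort(vapply(strsplit(part, ","), function(r)
      paste(sort(perm[as.integer(r)]), collapse = ","), ""))
    expect_equal(partp, remapped)
    # rename labels bijectively: partition unchanged
    tl <- t
    tl$labels <- chartr("abc", "xyz", tl$labels)
    expect_equal(root_partition(run_forward(build_rooted_view(tl))$classes$members),
                 part)
    # shuffling edge rows / orientations changes nothing in unordered mode
    e <- t$edges[sample(nrow(t$edges)), , drop = FALSE]
    flip <- sample(c(TRUE, FALSE), nrow(e), replace = TRUE)
    e[flip, ] <- e[flip, 2:1]
    ts <- labelled_tree(e, t$labels)
    expect_equal(root_partition(run_forward(build_rooted_view(ts))$classes$members),
                 part)
  }
})

test_that("a three-node path with equal leaf labels yields one frequency-2 class", {
  fw <- run_forward(build_rooted_view(path_tree(c("x", "y", "x"))))
  leaf_cls <- fw$classes[fw$classes$frequency == 2L, ]
  expect_equal(nrow(leaf_cls), 1L)
  expect_equal(leaf_cls$members[[1]]$root, c(1L, 3L))
})
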