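test_that("Newick parsing assigns pre-order ids and keeps labels", {
  t <- parse_tree("((A,B)C,D)E;")
  expect_equal(t$n, 5L)
  expect_equal(t$labels, c("E", "C", "A", "B", "D"))
  edge_set <- sort(apply(t$edges, 1, function(r) paste(sort(r), collapse = "-")))
  expect_equal(edge_set, c("1-2", "1-5", "2-3", "2-4"))  # E-C, E-D, C-A, C-B
})

test_that("degenerate Newick inputs parse", {
  t1 <- parse_tree("A;")
  expect_equal(t1$n, 1L)
  expect_equal(t1$labels, "A")
  t2 <- parse_tree("(B)A;")                # unifurcation
  expect_equal(t2$labels, c("A", "B"))
  t3 <- parse_tree("'a b';")
  expect_equal(t3$labels, "a b")
})

test_that("malformed or unlabelled input is rejected with a clear error", {
  expect_error(parse_tree("((A,B)C;"), "parse error")
  expect_error(parse_tree("(A,B)C));"), "unmatched")
  expect_error(parse_tree("(A,B);"), "missing label")
  expect_error(parse_tree("((,),D)E;"), "missing label")
})

test_that("topology-only Newick is accepted in unlabelled mode", {
  t <- parse_tree("((,),(,));", unlabelled = TRUE)
  expect_equal(t$n, 7L)
  expect_true(all(t$labels == "*"))
})

test_that("edge-list format round-trips the packaged fixture bit-exactly", {
  path <- system.file("extdata", "fixture28.tsv", package = "treerepeats")
  t <- parse_tree(path, format = "edgelist", file = TRUE)
  ref <- fixture_tree()
  expect_equal(t$n, 28L)
  expect_equal(nrow(t$edges), 27L)
  expect_identical(t$labels, ref$labels)
  expect_identical(t$adj, ref$adj)
  expect_identical(write_edgelist(t),
                   paste(readLines(path, warn = FALSE), collapse = "\n"))
})

test_that("Newick fixture reproduces the frozen node numbering", {
  path <- system.file("extdata", "fixture28.nwk", package = "treerepeats")
  t <- parse_tree(path, file = TRUE)
  expect_identical(t$labels, fixture_tree()$labels)
  expect_identical(t$adj, fixture_tree()$adj)
})

test_that("write/parse round-trip preserves the labelled shape", {
  for (s in 1:10) {
    t <- random_tree(sample.int(40, 1), sample.int(4, 1), seed = s)
    t2 <- parse_tree(write_newick(t, root = 1L))
    expect_equal(t2$n, t$n)
    expect_equal(sort(t2$labels), sort(t$labels))
    # rooted at the same written root, the shapes must be equal
    expect_identical(canonical_form(t2, 1L), canonical_form(t, 1L))
  }
})

test_that("structural validation rejects broken inputs", {
  expect_error(labelled_tree(rbind(c(1, 2)), c("a", "b", "c")), "structure error")
  expect_error(labelled_tree(rbind(c(1, 2), c(1, 2)), c("a", "b", "c")),
               "disconnected")
  expect_error(labelled_tree(rbind(c(1, 2), c(2, 3), c(3, 1)),
                             c("a", "b", "c")), "structure error")
  expect_error(labelled_tree(rbind(c(1, 4)), c("a", "b")), "outside")
  expect_error(labelled_tree(matrix(integer(), 0, 2), c("a", NA)),
               "missing label")
})

test_that("repeat reports are deterministic and ordered", {
  scan <- subtree_repeats(fixture_tree())
  tsv <- write_repeats(scan$classes, format = "tsv")
  lines <- strsplit(tsv, "\n")[[1]]
  expect_equal(lines[1], "kind\tclass_id\tfrequency\tmembers")
  kinds <- vapply(strsplit(lines[-1], "\t"), `[`, "", 1L)
  expect_true(!is.unsorted(match(kinds, c("non-overlapping", "overlapping", "total"))))
  ids <- as.integer(vapply(strsplit(lines[-1], "\t"), `[`, "", 2L))
  expect_true(all(tapply(ids, kinds, function(x) !is.unsorted(x))))
  # the worked overlapping class appears with its members ordered by root
  expect_true(any(grepl("^overlapping\t\\d+\t2\t2:4;9:12$", lines)))

  js <- jsonlite::fromJSON(write_repeats(scan$classes, format = "json"),
                           simplifyVector = FALSE)
  expect_equal(js$schema, 1L)
  expect_equal(length(js$classes), nrow(scan$classes))

  empty <- scan$classes[0, ]
  expect_equal(strsplit(write_repeats(empty, "tsv"), "\n")[[1]],
               "kind\tclass_id\tfrequency\tmembers")
  expect_equal(jsonlite::fromJSON(write_repeats(empty, "json"))$classes,
               list())
})
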