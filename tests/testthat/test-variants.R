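test_that("rooted mode loops over all heights of the chosen root", {
  # subtree hanging below node 2 of the worked-example tree, rooted at 2
  sub2 <- induced_subtree(fixture_tree(), 2L, 1L)
  fw <- run_rooted(sub2, 1L)
  # leaves still class by label; the (a c b)-cherry root has no partner here
  cherry <- which(sub2$labels == "c" & lengths(sub2$adj) == 4L)
  cls <- fw$classes[fw$classes$class_id == fw$node_class[cherry], ]
  expect_equal(cls$frequency, 1L)
  b_leaves <- which(sub2$labels == "b" & lengths(sub2$adj) == 1L)
  expect_equal(length(unique(fw$node_class[b_leaves])), 1L)
  # single node
  fw1 <- run_rooted(path_tree("a"), 1L)
  expect_equal(fw1$classes$frequency, 1L)
  # rooting a central tree at its centre reproduces the unrooted forward stage
  t <- star_tree("h", c("x", "x", "y"))
  expect_equal(run_rooted(t, 1L)$node_class,
               run_forward(build_rooted_view(t))$node_class)
})

test_that("ordered mode distinguishes child orders that unordered mode merges", {
  # two internal nodes whose children (a, c) appear in opposite orders
  t <- parse_tree("((a,c)x,(c,a)x)r;")
  un <- run_rooted(t, 1L)
  or <- run_ordered(t, 1L)
  x_nodes <- which(t$labels == "x")
  expect_equal(un$node_class[x_nodes[1]], un$node_class[x_nodes[2]])
  expect_false(or$node_class[x_nodes[1]] == or$node_class[x_nodes[2]])
  # mirror-image caterpillars: one unordered class, two ordered classes
  t2 <- parse_tree("(((p,q)m,(q,p)m)s)w;")
  m_nodes <- which(t2$labels == "m")
  expect_equal(length(unique(run_rooted(t2, 1L)$node_class[m_nodes])), 1L)
  expect_equal(length(unique(run_ordered(t2, 1L)$node_class[m_nodes])), 2L)
  # identical children: ordered partition equals unordered partition
  t3 <- parse_tree("((a,a)x,(a,a)x)r;")
  expect_equal(run_ordered(t3, 1L)$node_class, run_rooted(t3, 1L)$node_class)
})

test_that("ordered classes always refine the unordered rooted classes", {
  for (s in 1:6) {
    t <- random_tree(sample.int(80, 1), 2L, seed = 600 + s)
    root <- sample.int(t$n, 1L)
    un <- run_rooted(t, root)$node_class
    or <- run_ordered(t, root)$node_class
    # same ordered class => same unordered class
    for (cl in unique(or)) {
      expect_equal(length(unique(un[or == cl])), 1L)
    }
  }
})

test_that("unlabelled mode classes reflect topology only", {
  st <- run_unlabelled(star_tree("h", letters[1:5]))
  leaf_cls <- st$forward$classes[st$forward$classes$height == 0L, ]
  expect_equal(leaf_cls$frequency, 5L)
  # path of four identical nodes: the two end leaves are co-classed
  p4 <- subtree_repeats(path_tree(rep("n", 4)))
  expect_equal(p4$forward$node_class[1], p4$forward$node_class[4])
  # erasing the fixture's labels coarsens (or keeps) the partition
  lab <- subtree_repeats(fixture_tree())$forward$node_class
  unl <- run_unlabelled(fixture_tree())$forward$node_class
  expect_equal(unl[22], unl[27])     # co-classed nodes stay co-classed
  for (cl in unique(lab)) {
    expect_equal(length(unique(unl[lab == cl])), 1L)
  }
})

test_that("forest mode clusters equal subtrees across trees", {
  f <- list(parse_tree("((p,q)m,r)s;"), parse_tree("((p,q)m,r)s;"))
  fw <- run_forest(f)
  off <- attr(fw, "offsets")
  expect_equal(fw$node_class[1L], fw$node_class[off[2] + 1L])  # roots co-classed
  expect_true(all(fw$classes$frequency %% 2L == 0L))
  # the worked-example subtrees below nodes 2 and 9 are equal trees
  t <- fixture_tree()
  f2 <- list(induced_subtree(t, 2L, 1L), induced_subtree(t, 9L, 1L))
  fw2 <- run_forest(f2)
  expect_equal(fw2$node_class[1L], fw2$node_class[attr(fw2, "offsets")[2] + 1L])
  # two distinct single-node trees stay apart
  f3 <- list(path_tree("a"), path_tree("b"))
  fw3 <- run_forest(f3)
  expect_equal(length(unique(fw3$node_class)), 2L)
  expect_error(run_forest(list()), "empty")
})

test_that("forest of k copies gives frequencies divisible by k", {
  for (k in 2:4) {
    base <- random_tree(25, 3, seed = 700 + k)
    fw <- run_forest(rep(list(base), k))
    expect_true(all(fw$classes$frequency %% k == 0L))
  }
})
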