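#' Forward stage on a rooted tree
#'
#' In a rooted tree only non-overlapping repeats can occur, so the forward
#' stage alone suffices; the level loop runs over all heights `0..h(root)` of
#' the chosen root instead of stopping at half the diameter.
#'
#' @param tree a [labelled_tree()].
#' @param root node id to root at.
#' @return A [run_forward()] result.
#' @export
run_rooted <- function(tree, root) {
  run_forward(build_rooted_view(tree, root = root))
}

#' Forward stage on a rooted ordered tree
#'
#' As [run_rooted()], but the order of children (taken from the input
#' adjacency order) is significant: the within-string bucket sort is omitted,
#' so two subtrees repeat only if label and ordered child-class sequences
#' match.
#'
#' @inheritParams run_rooted
#' @return A [run_forward()] result.
#' @export
run_ordered <- function(tree, root) {
  run_forward(build_rooted_view(tree, root = root, ordered = TRUE))
}

#' Two-stage pipeline on an unlabelled tree
#'
#' An unlabelled tree is a labelled tree with a single uniform symbol: all
#' labels are replaced by `"*"` and the standard unrooted two-stage pipeline
#' is run, so the class partition reflects topology only.
#'
#' @param tree a [labelled_tree()] (labels ignored).
#' @return A [subtree_repeats()] scan object.
#' @export
run_unlabelled <- function(tree) {
  tree$labels[] <- "*"
  subtree_repeats(tree)
}

#' Forward stage over a forest of rooted trees
#'
#' Computes subtree repeats across all trees of a forest by the virtual-root
#' construction: the roots of all member trees are connected to one virtual
#' root and the forward stage is run on the combined tree, so equal subtrees
#' from different trees fall into one class.  Node ids are made globally
#' unique by offsetting each member tree's ids by the sizes of its
#' predecessors; the offsets are returned so members can be mapped back.
#'
#' @param forest list of [labelled_tree()] values (class `tree_forest`
#'   accepted); each member is taken as rooted at its node 1.
#' @param roots optional integer vector of per-tree root ids (default all 1).
#' @return A [run_forward()] result over the combined tree, with attributes
#'   `offsets` (id offset per member tree) and `tree_of` (member index per
#'   global node id).
#' @export
#' @examples
#' f <- list(parse_tree("(A,B)C;"), parse_tree("(A,B)C;"))
#' fw <- run_forest(f)
#' fw$node_class[1] == fw$node_class[4]   # the two roots share a class
run_forest <- function(forest, roots = NULL) {
  if (inherits(forest, "labelled_tree")) forest <- list(forest)
  k <- length(forest)
  if (k == 0L) stop("empty forest", call. = FALSE)
  if (is.null(roots)) roots <- rep(1L, k)
  sizes <- vapply(forest, function(t) t$n, 1L)
  offsets <- c(0L, cumsum(sizes))[seq_len(k)]
  n <- sum(sizes)
  labels <- unlist(lapply(forest, function(t) t$labels))
  edges <- do.call(rbind, lapply(seq_len(k), function(i)
    forest[[i]]$edges + offsets[i]))
  if (is.null(edges)) edges <- matrix(integer(), 0L, 2L)
  tree <- structure(
    list(n = n, labels = labels, edges = edges,
         adj = adjacency_list(n, edges)),
    class = "labelled_tree")
  global_roots <- roots + offsets
  # virtual root above all member roots: reuse the bicentral machinery by
  # building parent/children/heights directly
  parent <- rep(NA_integer_, n)
  children <- rep(list(integer()), n + 1L)
  children[[n + 1L]] <- global_roots
  parent[global_roots] <- n + 1L
  visit <- integer(n); vo <- 0L
  for (r in global_roots) {
    stack <- r
    while (length(stack) > 0L) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      vo <- vo + 1L; visit[vo] <- v
      kids <- sort(tree$adj[[v]][!(tree$adj[[v]] %in% parent[v])])
      children[[v]] <- kids
      parent[kids] <- v
      stack <- c(stack, rev(kids))
    }
  }
  height <- integer(n)
  for (i in rev(seq_len(n))) {
    v <- visit[i]
    kids <- children[[v]]
    height[v] <- if (length(kids) == 0L) 0L else 1L + max(height[kids])
  }
  view <- structure(
    list(base = tree, root = n + 1L, virtual = TRUE, parent = parent,
         children = children, height = height, centres = global_roots,
         diameter = tree_diameter_forest(forest), is_bicentral = FALSE,
         ordered = FALSE),
    class = "rooted_view")
  fw <- run_forward(view)
  attr(fw, "offsets") <- offsets
  attr(fw, "tree_of") <- rep(seq_len(k), sizes)
  fw
}

tree_diameter_forest <- function(forest) {
  max(vapply(forest, tree_diameter, 1L))
}
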