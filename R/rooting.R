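#' Tree centres of an unrooted tree
#'
#' The centre is the set of nodes whose greatest distance to any other node is
#' minimal; a tree has either one centre (central tree) or two adjacent
#' centres (bicentral tree).  Computed by iterative simultaneous leaf removal,
#' which strips one layer of leaves per round until one or two nodes remain.
#'
#' @param tree a [labelled_tree()].
#' @return Integer vector of 1 or 2 node ids (ascending).
#' @export
#' @examples
#' find_centres(parse_tree("(A,(B,(C,D)E)F)G;"))
find_centres <- function(tree) {
  n <- tree$n
  if (n <= 2L) return(seq_len(n))
  deg <- vapply(tree$adj, length, 1L)
  alive <- rep(TRUE, n)
  remaining <- n
  layer <- which(deg == 1L)
  while (remaining > 2L) {
    alive[layer] <- FALSE
    remaining <- remaining - length(layer)
    nxt <- integer()
    for (v in layer) {
      for (u in tree$adj[[v]]) {
        if (alive[u]) {
          deg[u] <- deg[u] - 1L
          if (deg[u] == 1L) nxt <- c(nxt, u)
        }
      }
    }
    layer <- nxt
  }
  sort(which(alive))
}

#' Diameter of an unrooted tree
#'
#' Number of edges on the longest path between any two leaves, computed with
#' the classic double-BFS sweep (BFS from any leaf to the farthest node, then
#' BFS again from there).
#'
#' @param tree a [labelled_tree()].
#' @return Non-negative integer.
#' @export
tree_diameter <- function(tree) {
  if (tree$n == 1L) return(0L)
  far <- bfs_dist(tree, 1L)
  a <- which.max(far)
  max(bfs_dist(tree, a))
}

bfs_dist <- function(tree, from) {
  n <- tree$n
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  queue <- from; head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    for (u in tree$adj[[v]]) {
      if (is.na(dist[u])) {
        dist[u] <- dist[v] + 1L
        queue <- c(queue, u)
      }
    }
  }
  dist
}

#' Rooted view of a tree
#'
#' Builds the directed version of an unrooted tree used by both stages: the
#' tree is rooted at its centre, or — for a bicentral tree — at a *virtual
#' root* placed above the two centres (the edge between the centres is not
#' traversed downward).  Alternatively an explicit real root can be supplied
#' (rooted-tree mode).  Heights are edge counts to the deepest leaf below a
#' node.
#'
#' The virtual root is represented by the sentinel id `n + 1`; it carries no
#' label, has no height entry in the real-node partition, and never appears in
#' reported repeat-class members.
#'
#' @param tree a [labelled_tree()].
#' @param root optional real node id to root at, bypassing centre rooting.
#' @param ordered keep children in edge-input (adjacency) order instead of
#'   ascending id; used by the ordered-tree variant.
#' @return An object of class `rooted_view` with fields `base`, `root`,
#'   `virtual` (flag), `parent` (integer vector, `NA` at the root and, for
#'   bicentral trees, virtual-root id at the centres), `children` (list over
#'   `1..n(+1)`), `height`, `centres`, `diameter`, `is_bicentral`.
#' @export
build_rooted_view <- function(tree, root = NULL, ordered = FALSE) {
  n <- tree$n
  centres <- find_centres(tree)
  diam <- tree_diameter(tree)
  if (is.null(root)) {
    bicentral <- length(centres) == 2L
    root_id <- if (bicentral) n + 1L else centres[1L]
    top <- if (bicentral) centres else root_id
  } else {
    root <- as.integer(root)
    if (root < 1L || root > n) stop("unknown root id ", root, call. = FALSE)
    bicentral <- FALSE
    root_id <- root
    top <- root_id
  }
  virtual <- root_id > n
  parent <- rep(NA_integer_, n)
  children <- rep(list(integer()), n + 1L)
  if (virtual) {
    children[[root_id]] <- top
    parent[top] <- root_id
  }
  # iterative DFS from the top real nodes, blocking the centre-centre edge
  visit_order <- integer(n)
  vo <- 0L
  for (t_ in top) {
    stack <- t_
    while (length(stack) > 0L) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      vo <- vo + 1L; visit_order[vo] <- v
      nb <- tree$adj[[v]]
      block <- parent[v]                                  # NA for a real root
      if (virtual && v %in% top) block <- c(block, top)   # centre-centre edge
      kids <- nb[!(nb %in% block)]
      if (!ordered) kids <- sort(kids)
      children[[v]] <- kids
      parent[kids] <- v
      for (k in rev(kids)) stack <- c(stack, k)
    }
  }
  if (vo != n) stop("internal error: rooted traversal missed nodes", call. = FALSE)
  # heights in reverse visit order (children before parents)
  height <- integer(n)
  for (i in rev(seq_len(n))) {
    v <- visit_order[i]
    kids <- children[[v]]
    height[v] <- if (length(kids) == 0L) 0L else 1L + max(height[kids])
  }
  structure(
    list(base = tree, root = root_id, virtual = virtual, parent = parent,
         children = children[seq_len(if (virtual) n + 1L else n)],
         height = height, centres = centres, diameter = diam,
         is_bicentral = length(centres) == 2L, ordered = ordered),
    class = "rooted_view"
  )
}

#' @export
print.rooted_view <- function(x, ...) {
  cat("<rooted_view> ", x$base$n, " nodes, diameter ", x$diameter,
      if (x$virtual) ", virtual root over centres " else ", rooted at ",
      if (x$virtual) toString(x$centres) else x$root,
      ", max height ", max(x$height), "\n", sep = "")
  invisible(x)
}

#' Node set of a full subtree T(v, u)
#'
#' Returns the ids of the component containing `v` after removing edge
#' `{v, u}`; with `u = NA` the whole tree (rooted at `v`) is returned.
#'
#' @param tree a [labelled_tree()].
#' @param v subtree root.
#' @param u removed neighbour, or `NA` for the whole tree.
#' @return Integer vector of node ids.
#' @export
subtree_nodes <- function(tree, v, u = NA) {
  keep <- integer()
  stack <- v
  seen <- logical(tree$n)
  seen[v] <- TRUE
  if (!is.na(u)) seen[u] <- TRUE
  while (length(stack) > 0L) {
    w <- stack[length(stack)]; stack <- stack[-length(stack)]
    keep <- c(keep, w)
    nb <- tree$adj[[w]]
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    stack <- c(stack, nb)
  }
  sort(keep)
}
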