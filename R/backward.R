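#' Backward stage: all overlapping and total subtree repeats
#'
#' Top-down recursion over the forward-stage identifiers.  A queue of node
#' sets starts with the (possibly virtual) root.  For each dequeued set `U`
#' the forward identifiers of all children of nodes in `U` are collected,
#' remapped to a dense range and bucket-sorted; each maximal group of children
#' sharing an identifier is a sibling/child repeat and is enqueued.  A group
#' `{u_1, ..., u_k}` with `k >= 2` yields two classes: the *total* repeat of
#' the whole-tree rootings at the `u_i`, and the *overlapping* repeat of the
#' trees `T(parent(u_i), u_i)` (rooted at the parent with the edge to `u_i`
#' removed).  Singleton groups are enqueued so the recursion continues below
#' non-repeating nodes, but emit nothing unless `emit_singletons` is set.
#' For a bicentral tree the group of the two centres (identifiers matching)
#' yields only the total repeat — the virtual root is not a real node, so no
#' overlapping class exists there.
#'
#' @param view a [build_rooted_view()] result (centre-rooted).
#' @param fwd the matching [run_forward()] result.
#' @param emit_singletons also emit frequency-1 groups (debugging aid).
#' @return An object of class `backward_result` with fields `classes` (tibble
#'   of overlapping and total repeat classes; members are
#'   (root, removed-neighbour) tuples, `neighbour == root` for totals),
#'   `enqueued` (count of real-node enqueue events; equals `n`), and `ops`.
#' @export
#' @examples
#' view <- build_rooted_view(fixture_tree())
#' bk <- run_backward(view, run_forward(view))
#' dplyr::filter(bk$classes, kind == "overlapping", frequency == 2)
run_backward <- function(view, fwd, emit_singletons = FALSE) {
  tree <- view$base
  n <- tree$n
  if (anyNA(fwd$node_class))
    stop("internal error: forward result leaves nodes unclassified",
         call. = FALSE)
  queue <- list(view$root)          # sets of nodes; root may be virtual
  head <- 1L
  enqueued <- sum(queue[[1L]] <= n)
  ops <- 0L
  next_id <- fwd$next_id
  rows <- list()
  while (head <= length(queue)) {
    U <- queue[[head]]; head <- head + 1L
    kids <- integer(); pars <- integer()
    for (v in sort(U)) {
      ch <- if (v <= length(view$children)) view$children[[v]] else integer()
      kids <- c(kids, ch)
      pars <- c(pars, rep(v, length(ch)))
    }
    if (length(kids) == 0L) next
    ids <- fwd$node_class[kids]
    ops <- ops + length(kids)
    # first-occurrence remap to 1..|I|, then stable bucket sort of the
    # (identifier, node) tuples by remapped identifier
    dense <- match(ids, unique(ids))
    m <- max(dense)
    buckets <- rep(list(integer()), m)
    for (j in seq_along(kids))
      buckets[[dense[j]]] <- c(buckets[[dense[j]]], j)
    ops <- ops + length(kids) + m
    for (b in seq_len(m)) {
      grp <- buckets[[b]]
      members <- kids[grp]
      queue[[length(queue) + 1L]] <- members
      enqueued <- enqueued + length(members)
      if (length(members) < 2L && !emit_singletons) next
      par <- pars[grp]
      o <- order(members)
      members <- members[o]; par <- par[o]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        kind = "total", class_id = next_id,
        frequency = length(members),
        members = list(tibble::tibble(root = members, neighbour = members))
      )
      next_id <- next_id + 1L
      if (all(par <= n)) {            # parent is a real node
        oo <- order(par, members)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          kind = "overlapping", class_id = next_id,
          frequency = length(members),
          members = list(tibble::tibble(root = par[oo], neighbour = members[oo]))
        )
        next_id <- next_id + 1L
      }
    }
  }
  classes <- if (length(rows) > 0L) dplyr::bind_rows(rows) else
    tibble::tibble(kind = character(), class_id = integer(),
                   frequency = integer(), members = list())
  structure(list(classes = classes, enqueued = enqueued, ops = ops,
                 next_id = next_id),
            class = "backward_result")
}

#' @export
print.backward_result <- function(x, ...) {
  cat("<backward_result> ",
      sum(x$classes$kind == "overlapping"), " overlapping and ",
      sum(x$classes$kind == "total"), " total repeat classes\n", sep = "")
  invisible(x)
}

#' Nodes on trivial paths
#'
#' Whenever a non-overlapping subtree repeats with frequency 1, every node on
#' the path from its root up to (and including) the nearest tree centre also
#' roots a frequency-1 class; such nodes are *trivial-path* nodes.  This
#' returns their union, for use as a test predicate: every member tree of an
#' overlapping repeat with frequency above 1 must contain all of them.
#'
#' @param view a [build_rooted_view()] result.
#' @param fwd the matching [run_forward()] result.
#' @return Sorted integer vector of node ids.
#' @export
trivial_path_nodes <- function(view, fwd) {
  n <- view$base$n
  roots1 <- unlist(lapply(
    which(fwd$classes$frequency == 1L),
    function(i) fwd$classes$members[[i]]$root))
  out <- logical(n)
  for (r in roots1) {
    v <- r
    repeat {
      out[v] <- TRUE
      if (v %in% view$centres) break
      p <- view$parent[v]
      if (is.na(p) || p > n) break
      v <- p
    }
  }
  which(out)
}
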