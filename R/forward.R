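#' Partition the real nodes of a rooted view by height
#'
#' Returns the array of height queues used by the forward stage: queue `i`
#' (list element `i + 1`) holds all real nodes of height `i`, in ascending
#' node-id order.  For a centre-rooted view the queues cover levels
#' `0..floor(d/2)`; the virtual root of a bicentral tree is excluded.
#'
#' @param view a [build_rooted_view()] result.
#' @return List of integer vectors, element `i + 1` = nodes of height `i`.
#' @export
partition_by_height <- function(view) {
  hmax <- max(view$height)
  lapply(0:hmax, function(h) sort(which(view$height == h)))
}

#' Assign integer identifiers to the label alphabet
#'
#' Bijection from the symbols occurring in the tree to `1..|Sigma|`, numbered
#' by first occurrence scanning nodes in ascending id order.
#'
#' @param tree a [labelled_tree()].
#' @return Named integer vector mapping symbol to identifier.
#' @export
assign_label_identifiers <- function(tree) {
  syms <- unique(tree$labels)
  stats::setNames(seq_along(syms), syms)
}

new_level_trace <- function(level, nodes) {
  structure(list(level = level, nodes = nodes, S = NULL, R = NULL,
                 R_sorted = NULL, R_lex = NULL, lex_order = NULL,
                 assigned = NULL),
            class = "level_trace")
}

#' @export
print.level_trace <- function(x, ...) {
  fmt <- function(ss) paste(vapply(ss, paste, "", collapse = " "), collapse = ",")
  cat("height ", x$level, "\n", sep = "")
  if (!is.null(x$S))        cat("  strings:   S   ", fmt(x$S), "\n", sep = "")
  if (!is.null(x$R))        cat("  remapping: R   ", fmt(x$R), "\n", sep = "")
  if (!is.null(x$R_sorted)) cat("  sorting:   R'  ", fmt(x$R_sorted), "\n", sep = "")
  if (!is.null(x$R_lex))    cat("  repeats:   R'' ", fmt(x$R_lex), "\n", sep = "")
  invisible(x)
}

#' Build the identifier strings of one height level
#'
#' For each node `v` of the level (in queue order) the string is the label
#' identifier of `v` followed by the class identifiers of `v`'s children, in
#' children-list order.  All strictly lower levels must already carry class
#' identifiers.
#'
#' @param view a [build_rooted_view()] result.
#' @param level height level (0 = leaves).
#' @param node_class integer vector of class identifiers assigned so far.
#' @param label_id label-identifier map from [assign_label_identifiers()].
#' @return A `level_trace` with field `S` populated (list of integer vectors).
#' @export
build_level_strings <- function(view, level, node_class, label_id) {
  nodes <- sort(which(view$height == level))
  trace <- new_level_trace(level, nodes)
  trace$S <- lapply(nodes, function(v) {
    kids <- view$children[[v]]
    cls <- node_class[kids]
    if (anyNA(cls))
      stop("internal-consistency error: child of node ", v,
           " has no class identifier yet", call. = FALSE)
    c(label_id[[view$base$labels[v]]], cls)
  })
  trace
}

# Reusable scratch state for the first-occurrence remap: an array A of size
# |T| + |Sigma| and a queue of touched cells, cleaned after each level so the
# allocation happens once per run.
new_scratch <- function(size) {
  env <- new.env(parent = emptyenv())
  env$A <- integer(size)
  env$ops <- 0L
  env
}

#' Remap the identifiers of a level to a dense range
#'
#' Replaces every identifier occurring in the level's strings by its
#' first-occurrence rank (reading the strings left to right), yielding
#' identifiers in `1..m` where `m` is the number of distinct identifiers at
#' this level.  Implemented with a single scratch array of size
#' `|T| + |Sigma|` whose touched cells are remembered in a queue and cleared
#' afterwards, so the step is linear in the total string length.
#'
#' @param trace a `level_trace` with `S` populated.
#' @param scratch internal reusable scratch state; allocated on demand.
#' @return The trace with `R` populated.
#' @export
remap_identifiers <- function(trace, scratch = NULL) {
  if (is.null(scratch)) {
    total <- max(unlist(trace$S), 1L)
    scratch <- new_scratch(total)
  }
  A <- scratch$A
  touched <- integer()
  m <- 0L
  trace$R <- lapply(trace$S, function(s) {
    out <- integer(length(s))
    for (i in seq_along(s)) {
      x <- s[i]
      if (x < 1L || x > length(A))
        stop("internal error: identifier ", x, " outside 1..", length(A),
             call. = FALSE)
      if (A[x] == 0L) {
        m <<- m + 1L
        A[x] <<- m
        touched <<- c(touched, x)
      }
      out[i] <- A[x]
    }
    out
  })
  scratch$ops <- scratch$ops + sum(lengths(trace$S)) + length(touched)
  A[touched] <- 0L                       # queue-driven cleanup
  scratch$A <- A
  trace$m <- m
  trace
}

#' Sort the identifiers within each remapped string
#'
#' Bucket sort over the dense range `1..m`: every (identifier, string-index)
#' tuple is dropped into its identifier bucket, then the buckets are swept in
#' ascending order and each identifier is appended back to its string on a
#' first-read-first-place basis.  Linear in the total string length plus `m`.
#'
#' @param trace a `level_trace` with `R` populated.
#' @return The trace with `R_sorted` populated.
#' @export
sort_within_strings <- function(trace) {
  m <- if (!is.null(trace$m)) trace$m else max(unlist(trace$R), 1L)
  buckets <- rep(list(integer()), m)
  for (k in seq_along(trace$R)) {
    for (x in trace$R[[k]]) buckets[[x]] <- c(buckets[[x]], k)
  }
  fill <- lapply(lengths(trace$R), integer)
  pos <- integer(length(trace$R))
  for (x in seq_len(m)) {
    for (k in buckets[[x]]) {
      pos[k] <- pos[k] + 1L
      fill[[k]][pos[k]] <- x
    }
  }
  trace$R_sorted <- fill
  trace
}

# Stable MSD radix sort of a list of integer vectors; returns the permutation.
# Shorter strings precede any extension; equal strings keep input order.
radix_lexsort <- function(strs, count_env = NULL) {
  ops <- 0L
  rec <- function(idx, pos) {
    if (length(idx) <= 1L) return(idx)
    len <- lengths(strs[idx])
    ended <- idx[len < pos]
    live <- idx[len >= pos]
    if (length(live) == 0L) return(ended)
    vals <- vapply(live, function(i) strs[[i]][pos], 1L)
    ops <<- ops + length(live)
    maxv <- max(vals)
    buckets <- rep(list(integer()), maxv)
    for (j in seq_along(live))
      buckets[[vals[j]]] <- c(buckets[[vals[j]]], live[j])
    out <- ended
    for (b in seq_len(maxv))
      if (length(buckets[[b]]) > 0L) out <- c(out, rec(buckets[[b]], pos + 1L))
    out
  }
  perm <- rec(seq_along(strs), 1L)
  if (!is.null(count_env)) count_env$ops <- count_env$ops + ops
  perm
}

#' Lexicographically sort the level's strings
#'
#' Stable radix sort of the within-sorted strings as integer sequences; a
#' shorter string precedes any of its extensions.  Equal adjacent strings in
#' the result are exactly the level's repeat classes.
#'
#' @param trace a `level_trace` with `R_sorted` populated.
#' @return The trace with `R_lex` (sorted strings) and `lex_order` (the
#'   permutation of queue positions) populated.
#' @export
lexsort_strings <- function(trace) {
  perm <- radix_lexsort(trace$R_sorted)
  trace$lex_order <- perm
  trace$R_lex <- trace$R_sorted[perm]
  trace
}

#' Extract the repeat classes of one level
#'
#' Maximal runs of identical adjacent strings in the lexicographically sorted
#' list each form one equivalence class; classes receive consecutive
#' identifiers in sorted order starting at `next_id`, and every class records
#' its member tuples (root node, parent node or `NA` for a top-level root).
#'
#' @param trace a `level_trace` with `R_lex` populated.
#' @param next_id first unused class identifier.
#' @param view the [build_rooted_view()] the trace came from.
#' @param node_class integer vector of class identifiers assigned so far.
#' @return List with `classes` (tibble rows for this level), updated
#'   `node_class`, `next_id`, and the trace with `assigned` populated.
#' @export
extract_level_classes <- function(trace, next_id, view, node_class) {
  k <- length(trace$R_lex)
  key <- vapply(trace$R_lex, paste, "", collapse = " ")
  run_id <- integer(k)
  cls_ids <- integer(0)
  for (i in seq_len(k)) {
    if (i == 1L || key[i] != key[i - 1L]) {
      cls_ids <- c(cls_ids, next_id)
      next_id <- next_id + 1L
    }
    run_id[i] <- cls_ids[length(cls_ids)]
  }
  nodes_sorted <- trace$nodes[trace$lex_order]
  node_class[nodes_sorted] <- run_id
  n <- view$base$n
  members <- lapply(cls_ids, function(id) {
    roots <- nodes_sorted[run_id == id]
    par <- view$parent[roots]
    par[!is.na(par) & par > n] <- NA_integer_   # virtual root is not a node
    tibble::tibble(root = sort(roots),
                   neighbour = par[order(roots)])
  })
  classes <- tibble::tibble(
    kind = "non-overlapping",
    class_id = cls_ids,
    height = trace$level,
    frequency = vapply(members, nrow, 1L),
    members = members
  )
  trace$assigned <- stats::setNames(cls_ids,
                                    key[!duplicated(run_id)])
  list(classes = classes, node_class = node_class, next_id = next_id,
       trace = trace)
}

#' Forward stage: all non-overlapping subtree repeats
#'
#' Runs the bottom-up stage over every height level of a rooted view: build
#' the per-node identifier strings, remap their identifiers to a dense range,
#' bucket-sort within each string (skipped in ordered mode), radix-sort the
#' strings lexicographically, and read off maximal runs of equal strings as
#' the level's repeat classes.  Two nodes receive the same class identifier
#' exactly when their downward subtrees are equal (same topology and labels,
#' child order ignored in unordered mode).
#'
#' @param view a [build_rooted_view()] result.
#' @return An object of class `forward_result` with fields `label_id`,
#'   `node_class` (identifier per node, all `> |Sigma|`), `classes` (tibble of
#'   non-overlapping repeat classes), `traces` (one `level_trace` per level),
#'   `ops` (elementary-operation counter backing the linearity contract),
#'   `sigma`, and the originating `view`.
#' @export
#' @examples
#' fw <- run_forward(build_rooted_view(fixture_tree()))
#' fw$node_class[c(2, 9)]   # equal subtrees below the two centres' children
run_forward <- function(view) {
  tree <- view$base
  n <- tree$n
  label_id <- assign_label_identifiers(tree)
  sigma <- length(label_id)
  scratch <- new_scratch(n + sigma)
  counter <- new.env(parent = emptyenv()); counter$ops <- 0L
  node_class <- rep(NA_integer_, n)
  next_id <- sigma + 1L
  hmax <- max(view$height)
  traces <- vector("list", hmax + 1L)
  class_rows <- vector("list", hmax + 1L)
  for (lev in 0:hmax) {
    trace <- build_level_strings(view, lev, node_class, label_id)
    counter$ops <- counter$ops + sum(lengths(trace$S))
    trace <- remap_identifiers(trace, scratch)
    trace <- if (isTRUE(view$ordered)) { trace$R_sorted <- trace$R; trace }
             else sort_within_strings(trace)
    counter$ops <- counter$ops + sum(lengths(trace$R)) + trace$m
    perm <- radix_lexsort(trace$R_sorted, counter)
    trace$lex_order <- perm
    trace$R_lex <- trace$R_sorted[perm]
    step <- extract_level_classes(trace, next_id, view, node_class)
    node_class <- step$node_class
    next_id <- step$next_id
    traces[[lev + 1L]] <- step$trace
    class_rows[[lev + 1L]] <- step$classes
  }
  counter$ops <- counter$ops + scratch$ops + n
  structure(
    list(label_id = label_id, sigma = sigma,
         node_class = node_class,
         classes = dplyr::bind_rows(class_rows),
         traces = traces,
         next_id = next_id,
         ops = counter$ops,
         view = view),
    class = "forward_result"
  )
}

#' @export
print.forward_result <- function(x, ...) {
  rep_cls <- sum(x$classes$frequency >= 2L)
  cat("<forward_result> ", length(x$node_class), " nodes, |Sigma| = ",
      x$sigma, ", ", nrow(x$classes), " non-overlapping classes (",
      rep_cls, " with frequency >= 2)\n", sep = "")
  invisible(x)
}

#' Per-level trace table in the four-row worked-example layout
#'
#' Formats each level's `S`, `R`, `R'` and `R''` lists as comma-separated
#' strings of space-separated identifiers, one tibble row per (level, list).
#'
#' @param fwd a [run_forward()] result.
#' @return A tibble with columns `height`, `step`, `value`.
#' @export
trace_table <- function(fwd) {
  fmt <- function(ss) paste(vapply(ss, paste, "", collapse = " "), collapse = ",")
  rows <- lapply(fwd$traces, function(tr) {
    tibble::tibble(
      height = tr$level,
      step = c("S", "R", "R'", "R''"),
      value = c(fmt(tr$S), fmt(tr$R), fmt(tr$R_sorted), fmt(tr$R_lex))
    )
  })
  dplyr::bind_rows(rows)
}
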