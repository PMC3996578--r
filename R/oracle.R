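#' Canonical form of a full subtree
#'
#' Independent brute-force equality test used to verify both stages: the
#' encoding of a rooted (sub)tree is `"(" label "|" <child encodings> ")"`,
#' with the child encodings sorted (unordered mode) or kept in adjacency
#' order (ordered mode).  Two subtrees are equal — same topology and labels
#' under a bijection — exactly when their encodings are identical.  The
#' explicit delimiters keep multi-character labels from colliding.
#'
#' @param tree a [labelled_tree()] (a `rooted_view` is also accepted).
#' @param root subtree root `v`.
#' @param removed removed neighbour `u` of `T(v, u)`, or `NA` for the whole
#'   tree rooted at `v`.
#' @param ordered respect adjacency order of children instead of sorting.
#' @return Character scalar encoding.
#' @export
#' @examples
#' t <- fixture_tree()
#' canonical_form(t, 4, 2) == canonical_form(t, 12, 9)
canonical_form <- function(tree, root, removed = NA, ordered = FALSE) {
  if (inherits(tree, "rooted_view")) tree <- tree$base
  rec <- function(v, from) {
    nb <- tree$adj[[v]]
    nb <- nb[nb != from]
    if (length(nb) == 0L)
      return(paste0("(", tree$labels[v], "|)"))
    kid <- vapply(nb, rec, "", from = v)
    if (!ordered) kid <- sort(kid)
    paste0("(", tree$labels[v], "|", paste(kid, collapse = ""), ")")
  }
  rec(root, if (is.na(removed)) 0L else as.integer(removed))
}

# Memoized canonical encodings of every directed edge (v seen from u), so the
# all-subtrees brute force costs O(n) encode calls instead of O(n^2).
edge_encodings <- function(tree) {
  n <- tree$n
  memo <- new.env(parent = emptyenv())
  enc <- function(v, from) {
    key <- paste0(v, ".", from)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    nb <- tree$adj[[v]]
    nb <- nb[nb != from]
    out <- if (length(nb) == 0L) paste0("(", tree$labels[v], "|)")
    else paste0("(", tree$labels[v], "|",
                paste(sort(vapply(nb, enc, "", from = v)), collapse = ""), ")")
    memo[[key]] <- out
    out
  }
  list(enc = enc)
}

#' Brute-force subtree repeat classes
#'
#' Groups, by canonical form, (i) the downward subtrees of the centre-rooted
#' view, (ii) all upward subtrees `T(v, u)` with `u` a child of `v`, and
#' (iii) all `n` whole-tree rootings.  Acceptance oracle for the forward
#' stage (downward), and for the backward stage's overlapping (upward) and
#' total (rootings) classes.
#'
#' @param tree a [labelled_tree()].
#' @return List of three tibbles (`downward`, `upward`, `rootings`), each with
#'   columns `key`, `frequency`, `members` (root/neighbour tibbles).
#' @export
bruteforce_repeats <- function(tree) {
  view <- build_rooted_view(tree)
  n <- tree$n
  E <- edge_encodings(tree)
  group <- function(keys, roots, neighbours) {
    split_idx <- split(seq_along(keys), keys)
    tibble::tibble(
      key = names(split_idx),
      frequency = lengths(split_idx),
      members = lapply(split_idx, function(ix) {
        o <- ix[order(roots[ix])]
        tibble::tibble(root = roots[o], neighbour = neighbours[o])
      })
    )
  }
  # downward: T(v, parent(v)); the top node(s) use the blocked centre edge
  d_keys <- character(n); d_nb <- integer(n)
  for (v in seq_len(n)) {
    p <- view$parent[v]
    from <- if (is.na(p)) 0L else if (p > n) setdiff(view$centres, v) else p
    if (length(from) == 0L) from <- 0L
    d_keys[v] <- E$enc(v, from)
    d_nb[v] <- if (from == 0L) NA_integer_ else from
  }
  downward <- group(d_keys, seq_len(n), d_nb)
  # upward: T(v, u) for every real parent v and child u
  up_v <- integer(); up_u <- integer(); up_keys <- character()
  for (v in seq_len(n)) {
    for (u in view$children[[v]]) {
      up_v <- c(up_v, v); up_u <- c(up_u, u)
      up_keys <- c(up_keys, canonical_upward(tree, E, v, u))
    }
  }
  upward <- group(up_keys, up_v, up_u)
  # whole-tree rootings
  r_keys <- vapply(seq_len(n), function(v) canonical_upward(tree, E, v, 0L), "")
  rootings <- group(r_keys, seq_len(n), seq_len(n))
  list(downward = downward, upward = upward, rootings = rootings)
}

canonical_upward <- function(tree, E, v, u) {
  nb <- tree$adj[[v]]
  nb <- nb[nb != u]
  if (length(nb) == 0L) return(paste0("(", tree$labels[v], "|)"))
  paste0("(", tree$labels[v], "|",
         paste(sort(vapply(nb, function(w) E$enc(w, v), "")), collapse = ""),
         ")")
}
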