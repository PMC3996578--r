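# Shared comparison helpers and small tree builders.

member_key <- function(m) {
  m <- m[order(m$root, m$neighbour), , drop = FALSE]
  paste(sprintf("%d:%s", m$root, ifelse(is.na(m$neighbour), "-", m$neighbour)),
        collapse = ";")
}

# canonical set-of-classes representation: each class as its member tuples
class_set <- function(members_list) {
  sort(unname(vapply(members_list, member_key, "")))
}

# partition as sorted root-sets (ignores the removed-neighbour component)
root_partition <- function(members_list) {
  sort(unname(vapply(members_list,
                     function(m) paste(sort(m$root), collapse = ","), "")))
}

path_tree <- function(labels) {
  n <- length(labels)
  edges <- if (n == 1L) matrix(integer(), 0, 2) else cbind(1:(n - 1L), 2:n)
  labelled_tree(edges, labels)
}

star_tree <- function(hub_label, leaf_labels) {
  k <- length(leaf_labels)
  labelled_tree(cbind(rep(1L, k), 1L + seq_len(k)),
                c(hub_label, leaf_labels))
}

# rooted subtree below v (with the edge {v, u} removed), re-indexed pre-order
induced_subtree <- function(tree, v, u = NA) {
  keep <- subtree_nodes(tree, v, u)
  # pre-order ids starting from v
  old2new <- integer(tree$n)
  order_ids <- integer(length(keep))
  stack <- v; seen <- logical(tree$n)
  seen[v] <- TRUE; if (!is.na(u)) seen[u] <- TRUE
  k <- 0L
  while (length(stack) > 0L) {
    w <- stack[length(stack)]; stack <- stack[-length(stack)]
    k <- k + 1L
    old2new[w] <- k; order_ids[k] <- w
    nb <- sort(tree$adj[[w]])
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    stack <- c(stack, rev(nb))
  }
  edges <- matrix(integer(), 0L, 2L)
  for (w in order_ids) {
    for (x in tree$adj[[w]]) {
      if (old2new[w] > 0L && x %in% order_ids && old2new[w] < old2new[x])
        edges <- rbind(edges, c(old2new[w], old2new[x]))
    }
  }
  labelled_tree(edges, tree$labels[order_ids])
}

# apply a node-id permutation: node i becomes perm[i]
permute_ids <- function(tree, perm) {
  e <- tree$edges
  e[] <- perm[e]
  labels <- character(tree$n)
  labels[perm] <- tree$labels
  labelled_tree(e, labels)
}
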