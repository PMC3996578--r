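#' The 28-node worked-example tree
#'
#' The bicentral tree used throughout the documentation and tests: 28 nodes,
#' labels over `{a, b, c, d}`, centres at nodes 1 and 16, diameter 7.  Node
#' ids follow a pre-order traversal with node 1 designated as root, and are
#' shipped frozen so every trace row is reproducible.  The same tree is
#' available as plain-text fixtures `fixture28.nwk` and `fixture28.tsv` under
#' `inst/extdata`.
#'
#' @return A [labelled_tree()] with 28 nodes.
#' @export
#' @examples
#' find_centres(fixture_tree())
fixture_tree <- function() {
  edges <- matrix(c(
    1, 2,  1, 9,  1, 16,  2, 3,  2, 4,  2, 8,  4, 5,  4, 6,  4, 7,
    9, 10,  9, 11,  9, 12,  12, 13,  12, 14,  12, 15,  16, 17,  16, 18,
    16, 21,  18, 19,  18, 20,  21, 22,  21, 24,  21, 27,  22, 23,
    24, 25,  24, 26,  27, 28), ncol = 2L, byrow = TRUE)
  labels <- c("a", "a", "b", "c", "a", "c", "b", "d", "a", "d", "b", "c",
              "b", "c", "a", "b", "a", "b", "b", "c", "a", "a", "d", "b",
              "b", "c", "a", "d")
  labelled_tree(edges, labels)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  code
}

make_alphabet <- function(k, upper = FALSE) {
  pool <- if (upper) LETTERS else letters
  if (k <= length(pool)) pool[seq_len(k)]
  else paste0(if (upper) "S" else "s", seq_len(k))
}

#' Random labelled tree
#'
#' Uniform random attachment: node `i` (for `i >= 2`) attaches to a node
#' drawn uniformly from `1..i-1`; labels are i.i.d. uniform over an alphabet
#' of the requested size.  Deterministic for a given seed, and the caller's
#' RNG state is left untouched.
#'
#' @param n number of nodes (`>= 1`).
#' @param alphabet_size number of distinct symbols available.
#' @param seed optional integer seed.
#' @return A [labelled_tree()].
#' @export
random_tree <- function(n, alphabet_size = 4L, seed = NULL) {
  stopifnot(n >= 1L, alphabet_size >= 1L)
  with_seed(seed, {
    sigma <- make_alphabet(alphabet_size)
    labels <- sample(sigma, n, replace = TRUE)
    edges <- if (n == 1L) matrix(integer(), 0L, 2L)
    else cbind(vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L), 2:n)
    labelled_tree(edges, labels)
  })
}

#' Tree with planted subtree repeats
#'
#' Generates a random *motif* subtree and grafts `copies` disjoint copies of
#' it onto random nodes of a random *backbone* tree.  By default the motif
#' alphabet (lower case) is disjoint from the backbone alphabet (upper case),
#' so no equal subtree can arise outside the copies and the planted
#' non-overlapping class has frequency exactly `copies`; the planted roots
#' are recorded in attribute `"planted_roots"`.
#'
#' @param motif_size nodes per motif copy (`>= 1`).
#' @param copies number of grafted copies (`>= 2`).
#' @param filler_size backbone size (`>= 1`).
#' @param seed optional integer seed.
#' @param motif_alphabet,filler_alphabet symbol counts for the two parts.
#' @return A [labelled_tree()] of `filler_size + copies * motif_size` nodes
#'   with attributes `planted_roots` and `motif` (the motif as a
#'   `labelled_tree` rooted at its node 1).
#' @export
planted_repeat_tree <- function(motif_size, copies, filler_size = 5L,
                                seed = NULL, motif_alphabet = 3L,
                                filler_alphabet = 3L) {
  stopifnot(copies >= 2L, motif_size >= 1L, filler_size >= 1L)
  with_seed(seed, {
    motif <- random_tree(motif_size, motif_alphabet)
    backbone <- random_tree(filler_size, 1L)
    backbone$labels <- sample(make_alphabet(filler_alphabet, upper = TRUE),
                              filler_size, replace = TRUE)
    n <- filler_size + copies * motif_size
    labels <- c(backbone$labels, rep(motif$labels, copies))
    edges <- backbone$edges
    planted <- integer(copies)
    for (j in seq_len(copies)) {
      off <- filler_size + (j - 1L) * motif_size
      planted[j] <- off + 1L
      attach_at <- sample.int(filler_size, 1L)
      edges <- rbind(edges, c(attach_at, off + 1L),
                     if (motif_size > 1L) motif$edges + off)
    }
    out <- labelled_tree(edges, labels)
    attr(out, "planted_roots") <- planted
    attr(out, "motif") <- motif
    out
  })
}
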