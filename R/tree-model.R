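#' Construct a labelled tree
#'
#' A `labelled_tree` is an undirected, unordered, acyclic connected graph in
#' which every node carries a symbol from a finite alphabet.  Nodes are
#' identified by the dense integers `1..n`; labels need not be unique.  This is
#' the input object of every repeat-detection routine in the package.
#'
#' @param edges two-column integer matrix (or data frame) of undirected edges;
#'   a tree with `n` nodes must have exactly `n - 1` rows.  The row order is
#'   preserved and defines the neighbour order used by the ordered-tree mode.
#' @param labels character vector of length `n`; `labels[i]` is the symbol at
#'   node `i`.
#' @param n number of nodes; defaults to `length(labels)`.
#'
#' @return An object of class `labelled_tree` with fields `n`, `labels`,
#'   `edges` and a precomputed adjacency list `adj` (neighbours in edge-input
#'   order).
#' @export
#' @examples
#' labelled_tree(rbind(c(1, 2), c(1, 3)), c("a", "b", "b"))
labelled_tree <- function(edges, labels, n = length(labels)) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(integer(), 0L, 2L)
  storage.mode(edges) <- "integer"
  labels <- as.character(labels)
  if (nrow(edges) > 0L && (min(edges) < 1L || max(edges) > n))
    stop("structure error: edge endpoint outside 1..n", call. = FALSE)
  tree <- structure(
    list(n = as.integer(n), labels = labels, edges = edges,
         adj = adjacency_list(as.integer(n), edges)),
    class = "labelled_tree"
  )
  validate_labelled_tree(tree)
}

adjacency_list <- function(n, edges) {
  adj <- rep(list(integer()), n)
  for (k in seq_len(nrow(edges))) {
    u <- edges[k, 1L]; v <- edges[k, 2L]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  adj
}

#' Validate the structural invariants of a labelled tree
#'
#' Checks that node ids are `1..n`, that every node has exactly one label,
#' that `|E| = n - 1`, and that the edge set is connected (which together with
#' the edge count implies acyclicity).
#'
#' @param tree object as built by [labelled_tree()].
#' @return The validated tree, invisibly unchanged.
#' @export
validate_labelled_tree <- function(tree) {
  n <- tree$n
  if (n < 1L) stop("a tree needs at least one node", call. = FALSE)
  if (length(tree$labels) != n)
    stop("need exactly one label per node: ", length(tree$labels),
         " labels for ", n, " nodes", call. = FALSE)
  if (anyNA(tree$labels))
    stop("missing label on node(s) ", toString(which(is.na(tree$labels))),
         call. = FALSE)
  e <- tree$edges
  if (nrow(e) != n - 1L)
    stop("structure error: ", nrow(e), " edges for ", n,
         " nodes (need n - 1)", call. = FALSE)
  if (nrow(e) > 0L && (min(e) < 1L || max(e) > n))
    stop("structure error: edge endpoint outside 1..n", call. = FALSE)
  if (any(e[, 1L] == e[, 2L]))
    stop("structure error: self-loop", call. = FALSE)
  # connectivity by BFS from node 1; with n-1 edges this also rules out cycles
  seen <- logical(n)
  queue <- 1L; seen[1L] <- TRUE; head <- 1L
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L
    nb <- tree$adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  if (!all(seen))
    stop("structure error: graph is disconnected (node ",
         which(!seen)[1L], " unreachable)", call. = FALSE)
  invisible(tree)
}

#' @export
print.labelled_tree <- function(x, ...) {
  cat("<labelled_tree> ", x$n, " nodes, ",
      length(unique(x$labels)), " distinct labels (",
      toString(utils::head(sort(unique(x$labels)), 8L)), ")\n", sep = "")
  invisible(x)
}

#' Number of nodes of a labelled tree
#' @param x a `labelled_tree`.
#' @export
length.labelled_tree <- function(x) x$n

# ---- parsing ---------------------------------------------------------------

#' Read a labelled tree (or forest) from text
#'
#' Two formats are supported.  `"newick"` accepts standard Newick with names on
#' leaves *and* internal nodes (the names are the labels; branch lengths and
#' comments are ignored; quoted names are allowed).  Node ids `1..n` are
#' assigned by a pre-order traversal of the parsed tree, root first, children
#' in input order — the order nodes are first encountered while reading the
#' string.  `"edgelist"` is a header-free TSV with one `u<TAB>v` edge per line,
#' a blank line, then one `id<TAB>label` line per node; ids are 1-based and
#' taken verbatim, which lets a caller pin down node numbering exactly.
#'
#' A Newick string with empty names (topology-only input) is accepted when
#' `unlabelled = TRUE`: every node is then assigned the single uniform symbol
#' `"*"`.
#'
#' @param text character scalar with the serialized tree, or a file path when
#'   `file = TRUE`.
#' @param format `"newick"` or `"edgelist"`.
#' @param unlabelled assign the uniform symbol `"*"` to every node, ignoring
#'   any names present.
#' @param file treat `text` as a path and read it.
#' @return A [labelled_tree()]; for a multi-tree Newick file, a list of them
#'   (class `tree_forest`) with the parse-order root of each member recorded in
#'   attribute `"root"` (always node 1 under pre-order ids).
#' @export
#' @examples
#' parse_tree("((A,B)C,D)E;")
parse_tree <- function(text, format = c("newick", "edgelist"),
                       unlabelled = FALSE, file = FALSE) {
  format <- match.arg(format)
  if (file) text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  if (format == "newick") parse_newick(text, unlabelled = unlabelled)
  else parse_edgelist(text, unlabelled = unlabelled)
}

check_parens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("parse error at character ", i, ": unmatched ')'", call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("parse error at character ", nchar(text),
         ": ", depth, " unclosed '('", call. = FALSE)
  invisible(TRUE)
}

parse_newick <- function(text, unlabelled = FALSE) {
  text <- trimws(text)
  check_parens(text)
  trees <- strsplit(text, ";", fixed = TRUE)[[1]]
  trees <- trimws(trees)
  trees <- trees[nzchar(trees)]
  if (length(trees) == 0L) stop("parse error: empty Newick input", call. = FALSE)
  out <- lapply(trees, parse_newick_one, unlabelled = unlabelled)
  if (length(out) == 1L) out[[1]] else
    structure(out, class = "tree_forest")
}

parse_newick_one <- function(txt, unlabelled = FALSE) {
  if (!grepl(",", txt, fixed = TRUE)) {
    # no comma => at most one child per node: a chain with a single leaf
    # (ape cannot represent one-tip trees faithfully, so parse it directly)
    return(parse_newick_chain(txt, unlabelled))
  }
  if (unlabelled) {
    # name every anonymous node "*" so ape keeps the full topology
    txt <- gsub("([(,])(?=[,)])", "\\1*", paste0(txt, ";"), perl = TRUE)
    txt <- gsub("\\)(?=[,;)])", ")*", txt, perl = TRUE)
    phy <- ape::read.tree(text = txt)
    phy$tip.label <- rep("*", length(phy$tip.label))
    phy$node.label <- rep("*", phy$Nnode)
  } else {
    phy <- ape::read.tree(text = paste0(txt, ";"))
  }
  if (is.null(phy)) stop("parse error: invalid Newick string", call. = FALSE)
  phylo_to_labelled_tree(phy)
}

#' Convert an `ape` phylo object to a labelled tree
#'
#' Ids are reassigned by pre-order (root first, children in cladewise order);
#' tip and node labels become the node labels.
#'
#' @param phy a `phylo` object with `tip.label` and, for internal nodes,
#'   `node.label`.
#' @return A [labelled_tree()].
#' @export
phylo_to_labelled_tree <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  n <- ntip + nnode
  lab <- character(n)
  lab[seq_len(ntip)] <- phy$tip.label
  if (!is.null(phy$node.label) && length(phy$node.label) == nnode)
    lab[ntip + seq_len(nnode)] <- phy$node.label
  else if (nnode > 0L)
    lab[ntip + seq_len(nnode)] <- NA_character_
  kids <- rep(list(integer()), n)
  for (k in seq_len(nrow(phy$edge)))   # cladewise: input child order preserved
    kids[[phy$edge[k, 1L]]] <- c(kids[[phy$edge[k, 1L]]], phy$edge[k, 2L])
  root <- ntip + 1L
  # iterative pre-order walk assigning dense ids
  newid <- integer(n)
  edges_u <- integer(n - 1L); edges_v <- integer(n - 1L); ne <- 0L
  labels <- character(n)
  stack <- root; parent_new <- 0L
  pstack <- 0L
  next_id <- 0L
  while (length(stack) > 0L) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    p <- pstack[length(pstack)]; pstack <- pstack[-length(pstack)]
    next_id <- next_id + 1L
    newid[v] <- next_id
    labels[next_id] <- lab[v]
    if (p > 0L) {
      ne <- ne + 1L
      edges_u[ne] <- p; edges_v[ne] <- next_id
    }
    ch <- kids[[v]]
    for (c_ in rev(ch)) {          # reversed push => left-to-right visit order
      stack <- c(stack, c_)
      pstack <- c(pstack, next_id)
    }
  }
  if (anyNA(labels))
    stop("missing label on node(s) ", toString(which(is.na(labels))),
         " (internal nodes must be named, or use unlabelled mode)",
         call. = FALSE)
  if (any(!nzchar(labels)))
    stop("missing label on node(s) ", toString(which(!nzchar(labels))),
         " (empty names; use unlabelled mode for topology-only input)",
         call. = FALSE)
  labelled_tree(cbind(edges_u, edges_v, deparse.level = 0), labels)
}

# "((d)b)a" -> path a-b-d with pre-order ids from the outermost (root) node
parse_newick_chain <- function(txt, unlabelled = FALSE) {
  labs <- character()
  txt <- trimws(txt)
  while (startsWith(txt, "(")) {
    if (!endsWith_paren(txt))
      stop("parse error: malformed nested Newick '", txt, "'", call. = FALSE)
    close_at <- matching_paren(txt)
    lab <- trimws(substring(txt, close_at + 1L))
    labs <- c(labs, unquote_label(lab))
    txt <- trimws(substring(txt, 2L, close_at - 1L))
  }
  labs <- c(labs, unquote_label(txt))
  if (unlabelled) labs[] <- "*"
  if (any(!nzchar(labs)))
    stop("missing label on node(s) ", toString(which(!nzchar(labs))),
         " (empty names; use unlabelled mode for topology-only input)",
         call. = FALSE)
  n <- length(labs)
  edges <- if (n == 1L) matrix(integer(), 0L, 2L)
  else cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
  labelled_tree(edges, labs)
}

unquote_label <- function(s) sub("^'(.*)'$", "\\1", trimws(s))

matching_paren <- function(txt) {
  depth <- 0L
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth == 0L) return(i)
    }
  }
  stop("parse error: unbalanced parentheses", call. = FALSE)
}

endsWith_paren <- function(txt) grepl(")", txt, fixed = TRUE)

parse_edgelist <- function(text, unlabelled = FALSE) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines, which = "right")
  blank <- which(!nzchar(lines))
  if (length(blank) == 0L && length(lines) == 1L) {
    # single node: no edges, just one "id label" line
    edge_lines <- character()
    label_lines <- lines
  } else {
    if (length(blank) == 0L)
      stop("parse error: edge-list input needs a blank line between the ",
           "edge section and the label section", call. = FALSE)
    sep <- blank[1L]
    edge_lines <- lines[seq_len(sep - 1L)]
    label_lines <- lines[-seq_len(sep)]
    label_lines <- label_lines[nzchar(label_lines)]
  }
  parse_pair <- function(line, where, what) {
    f <- strsplit(line, "[\t ]+")[[1]]
    f <- f[nzchar(f)]
    if (length(f) != 2L)
      stop("parse error at ", what, " line ", where, ": need two fields, got '",
           line, "'", call. = FALSE)
    f
  }
  edges <- matrix(integer(), length(edge_lines), 2L)
  for (i in seq_along(edge_lines)) {
    f <- parse_pair(edge_lines[i], i, "edge")
    u <- suppressWarnings(as.integer(f))
    if (anyNA(u))
      stop("parse error at edge line ", i, ": non-integer id", call. = FALSE)
    edges[i, ] <- u
  }
  n <- length(label_lines)
  labels <- character(n)
  for (i in seq_along(label_lines)) {
    f <- parse_pair(label_lines[i], i, "label")
    id <- suppressWarnings(as.integer(f[1L]))
    if (is.na(id) || id < 1L || id > n)
      stop("parse error at label line ", i, ": id ", f[1L],
           " outside 1..", n, call. = FALSE)
    if (nzchar(labels[id]))
      stop("parse error at label line ", i, ": duplicate id ", id,
           call. = FALSE)
    labels[id] <- f[2L]
  }
  if (any(!nzchar(labels)))
    stop("missing label on node(s) ", toString(which(!nzchar(labels))),
         call. = FALSE)
  if (unlabelled) labels[] <- "*"
  labelled_tree(edges, labels)
}

# ---- writing ---------------------------------------------------------------

#' Serialize a labelled tree
#'
#' `write_newick()` emits Newick rooted at a chosen node with children in
#' ascending-id order; `write_edgelist()` emits the package's two-section TSV
#' edge-list format (edges, blank line, id/label table) which preserves node
#' ids exactly.
#'
#' @param tree a [labelled_tree()].
#' @param root node id used as Newick root (default 1).
#' @return A character scalar.
#' @export
write_newick <- function(tree, root = 1L) {
  quote_lab <- function(s)
    ifelse(grepl("[(),;:'\\s]", s), paste0("'", gsub("'", "''", s), "'"), s)
  rec <- function(v, from) {
    nb <- sort(setdiff(tree$adj[[v]], from))
    lab <- quote_lab(tree$labels[v])
    if (length(nb) == 0L) lab
    else paste0("(", paste(vapply(nb, rec, "", from = v), collapse = ","), ")", lab)
  }
  paste0(rec(root, 0L), ";")
}

#' @rdname write_newick
#' @export
write_edgelist <- function(tree) {
  e <- tree$edges
  paste(c(sprintf("%d\t%d", e[, 1L], e[, 2L]), "",
          sprintf("%d\t%s", seq_len(tree$n), tree$labels)),
        collapse = "\n")
}

#' Write a repeat-class report
#'
#' Serializes a table of repeat classes (as produced by the forward/backward
#' stages or [subtree_repeats()]) to JSON or TSV.  The output is deterministic:
#' classes are ordered by kind (non-overlapping, overlapping, total) then class
#' id, and the members of each class by root id.  TSV columns are
#' `kind`, `class_id`, `frequency`, `members`, with members rendered as
#' `root:neighbour` pairs separated by `;` (`neighbour` is `-` when the member
#' is a whole downward subtree with no removed neighbour).
#'
#' @param classes tibble with columns `kind`, `class_id`, `frequency`,
#'   `members` (list of data frames with columns `root`, `neighbour`).
#' @param format `"json"` or `"tsv"`.
#' @param path optional file path; when `NULL` the report is returned as a
#'   character scalar.
#' @param singletons keep frequency-1 classes (dropped by default).
#' @return The report text, invisibly when written to `path`.
#' @export
write_repeats <- function(classes, format = c("json", "tsv"), path = NULL,
                          singletons = TRUE) {
  format <- match.arg(format)
  classes <- sort_classes(classes)
  if (!singletons) classes <- classes[classes$frequency >= 2L, , drop = FALSE]
  if (format == "tsv") {
    member_str <- vapply(classes$members, function(m) {
      m <- m[order(m$root, m$neighbour), , drop = FALSE]
      nb <- ifelse(is.na(m$neighbour), "-", as.character(m$neighbour))
      paste(sprintf("%d:%s", m$root, nb), collapse = ";")
    }, "")
    out <- paste(c("kind\tclass_id\tfrequency\tmembers",
                   sprintf("%s\t%d\t%d\t%s", classes$kind, classes$class_id,
                           classes$frequency, member_str)),
                 collapse = "\n")
  } else {
    recs <- lapply(seq_len(nrow(classes)), function(i) {
      m <- classes$members[[i]]
      m <- m[order(m$root, m$neighbour), , drop = FALSE]
      list(kind = classes$kind[i],
           class_id = classes$class_id[i],
           frequency = classes$frequency[i],
           members = lapply(seq_len(nrow(m)), function(j)
             list(root = m$root[j],
                  neighbour = if (is.na(m$neighbour[j])) NULL else m$neighbour[j])))
    })
    out <- jsonlite::toJSON(list(schema = 1L, classes = recs),
                            auto_unbox = TRUE, pretty = TRUE, null = "null")
    out <- as.character(out)
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

kind_levels <- c("non-overlapping", "overlapping", "total")

sort_classes <- function(classes) {
  k <- match(classes$kind, kind_levels)
  classes[order(k, classes$class_id), , drop = FALSE]
}
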