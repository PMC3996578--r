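#' Find all full subtree repeats of a labelled tree
#'
#' One-call interface to the two-stage pipeline.  The tree is rooted at its
#' centre (with a virtual root for bicentral trees), the forward stage groups
#' all non-overlapping repeats bottom-up, and — in unrooted mode — the
#' backward stage derives all overlapping and total repeats from the forward
#' identifiers.
#'
#' @param tree a [labelled_tree()], or a character scalar parsed with
#'   [parse_tree()] (Newick assumed).
#' @param mode `"unrooted"` (default, both stages), `"rooted"` or `"ordered"`
#'   (forward stage only, rooted at `root`).
#' @param root required for rooted/ordered modes.
#' @param unlabelled replace all labels by the uniform symbol `"*"`.
#' @param emit_singletons emit frequency-1 groups from the backward stage.
#' @return An object of class `repeat_scan` with fields `tree`, `view`,
#'   `forward`, `backward` (`NULL` outside unrooted mode), and `classes`
#'   — one tibble over all kinds with columns `kind`, `class_id`, `height`
#'   (`NA` for backward classes), `frequency`, `members`.
#' @export
#' @examples
#' scan <- subtree_repeats(fixture_tree())
#' dplyr::filter(tidy(scan), frequency >= 2)
subtree_repeats <- function(tree, mode = c("unrooted", "rooted", "ordered"),
                            root = NULL, unlabelled = FALSE,
                            emit_singletons = FALSE) {
  mode <- match.arg(mode)
  if (is.character(tree)) tree <- parse_tree(tree, unlabelled = unlabelled)
  if (unlabelled) tree$labels[] <- "*"
  if (mode != "unrooted" && is.null(root))
    stop("mode '", mode, "' needs a --root node id", call. = FALSE)
  if (mode == "unrooted" && !is.null(root))
    stop("--root only applies to rooted/ordered modes", call. = FALSE)
  view <- switch(mode,
    unrooted = build_rooted_view(tree),
    rooted   = build_rooted_view(tree, root = root),
    ordered  = build_rooted_view(tree, root = root, ordered = TRUE))
  fwd <- run_forward(view)
  bwd <- if (mode == "unrooted")
    run_backward(view, fwd, emit_singletons = emit_singletons) else NULL
  classes <- fwd$classes
  if (!is.null(bwd) && nrow(bwd$classes) > 0L)
    classes <- dplyr::bind_rows(classes, bwd$classes)
  structure(list(tree = tree, view = view, forward = fwd, backward = bwd,
                 classes = sort_classes(classes), mode = mode),
            class = "repeat_scan")
}

#' @export
print.repeat_scan <- function(x, ...) {
  tab <- table(factor(x$classes$kind, kind_levels))
  cat("<repeat_scan> ", x$tree$n, " nodes (", x$mode, " mode)\n", sep = "")
  cat("  classes: ", paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
      "\n", sep = "")
  rep2 <- x$classes[x$classes$frequency >= 2L, ]
  cat("  with frequency >= 2: ", nrow(rep2), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a repeat scan into one row per repeat class
#'
#' @param x a [subtree_repeats()] result.
#' @param singletons keep frequency-1 classes.
#' @param ... unused.
#' @return Tibble with columns `kind`, `class_id`, `height`, `frequency`,
#'   `members` (list column of root/neighbour tibbles).
#' @method tidy repeat_scan
#' @export
tidy.repeat_scan <- function(x, singletons = TRUE, ...) {
  out <- x$classes
  if (!singletons) out <- out[out$frequency >= 2L, , drop = FALSE]
  tibble::as_tibble(out)
}

#' One-row summary of a repeat scan
#'
#' @param x a [subtree_repeats()] result.
#' @param ... unused.
#' @return Tibble with node count, alphabet size, diameter, centre count, and
#'   class counts per kind (total and with frequency at least 2).
#' @method glance repeat_scan
#' @export
glance.repeat_scan <- function(x, ...) {
  cls <- x$classes
  cnt <- function(kind, min_f = 1L)
    sum(cls$kind == kind & cls$frequency >= min_f)
  tibble::tibble(
    n = x$tree$n,
    sigma = length(unique(x$tree$labels)),
    diameter = x$view$diameter,
    n_centres = length(x$view$centres),
    non_overlapping = cnt("non-overlapping"),
    non_overlapping_rep = cnt("non-overlapping", 2L),
    overlapping = cnt("overlapping"),
    total = cnt("total"),
    forward_ops = x$forward$ops
  )
}

#' Plot the repeat-class frequency spectrum
#'
#' Bar chart of class frequencies split by repeat kind, a quick visual of how
#' much of the tree is shared structure.
#'
#' @param object a [subtree_repeats()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot repeat_scan
#' @export
autoplot.repeat_scan <- function(object, ...) {
  df <- tidy(object)
  df$kind <- factor(df$kind, kind_levels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frequency)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::facet_wrap(~kind, nrow = 1) +
    ggplot2::scale_x_continuous(breaks = function(l) unique(floor(pretty(l)))) +
    ggplot2::labs(x = "repetition frequency", y = "repeat classes",
                  title = "Subtree repeat spectrum") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
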