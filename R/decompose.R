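#' Construct a segment path
#'
#' An ordered run of trace points extracted from a neuron tree, labelled
#' with its segment class. Exactly coincident consecutive points are merged
#' (with a warning): duplicate points make chord-length parameters collide
#' and the interpolation problem ill-posed.
#'
#' @param points n x 3 numeric matrix of coordinates (micrometres), n >= 2.
#' @param seg_class one of `"primary"`, `"collateral"`, `"terminal"`.
#' @param neuron_id neuron identifier string.
#' @return Object of class `segment_path` with fields `points`, `seg_class`,
#'   `neuron_id`, `L` (cumulative chord length) and `n_points`.
#' @export
segment_path <- function(points, seg_class = c("primary", "collateral", "terminal"),
                         neuron_id = "") {
  seg_class <- match.arg(seg_class)
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("`points` must be an n x 3 matrix")
  if (nrow(points) >= 2) {
    dup <- c(FALSE, rowSums(diff(points)^2) == 0)
    if (any(dup)) {
      warning("merged ", sum(dup), " coincident consecutive trace point(s)")
      points <- points[!dup, , drop = FALSE]
    }
  }
  if (nrow(points) < 2) stop("degenerate segment: fewer than 2 distinct points")
  u <- cum_chord(points)
  structure(
    list(points = points, seg_class = seg_class, neuron_id = neuron_id,
         L = u[length(u)], n_points = nrow(points)),
    class = "segment_path"
  )
}

#' @export
print.segment_path <- function(x, ...) {
  cat("<segment_path> ", x$seg_class, ", ", x$n_points, " points, L = ",
      format(x$L), " um (", x$neuron_id, ")\n", sep = "")
  invisible(x)
}

# children index list and parent index vector for fast traversal
tree_index <- function(tree) {
  nodes <- tree$nodes
  pidx <- match(nodes$parent, nodes$id)
  children <- vector("list", nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    if (!is.na(pidx[i])) children[[pidx[i]]] <- c(children[[pidx[i]]], i)
  }
  # deterministic order: ascending child id
  children <- lapply(children, function(k) k[order(nodes$id[k])])
  list(nodes = nodes, pidx = pidx, children = children,
       root = which(nodes$parent == -1))
}

# Longest root-to-leaf path (by Euclidean path length) from node index
# `root_i`, optionally restricted to descend through `first_child` only.
# Ties broken by smallest leaf node id. Returns vector of node indices.
.longest_path_idx <- function(ix, root_i, first_child = NULL) {
  nodes <- ix$nodes
  xyz <- cbind(nodes$x, nodes$y, nodes$z)
  start_kids <- first_child %||% ix$children[[root_i]]
  if (length(start_kids) == 0) stop("no path: node has no descendants")
  best_len <- -Inf
  best_leaf <- NA_integer_
  parent_of <- integer(nrow(nodes))  # within this traversal
  dist <- numeric(nrow(nodes))
  stack <- start_kids
  parent_of[start_kids] <- root_i
  dist[start_kids] <- sqrt(colSums((t(xyz[start_kids, , drop = FALSE]) - xyz[root_i, ])^2))
  while (length(stack)) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- ix$children[[i]]
    if (length(kids) == 0) {
      if (dist[i] > best_len ||
          (dist[i] == best_len && nodes$id[i] < nodes$id[best_leaf])) {
        best_len <- dist[i]
        best_leaf <- i
      }
    } else {
      d <- sqrt(colSums((t(xyz[kids, , drop = FALSE]) - xyz[i, ])^2))
      dist[kids] <- dist[i] + d
      parent_of[kids] <- i
      stack <- c(stack, kids)
    }
  }
  path <- best_leaf
  while (path[1] != root_i) path <- c(parent_of[path[1]], path)
  path
}

#' Longest root-to-leaf path of a neuron tree
#'
#' Returns the root-to-leaf node sequence maximizing cumulative Euclidean
#' path length (not hop count), which makes the downstream arbor splitting
#' invariant to rigid transformations. Ties are broken deterministically in
#' favour of the leaf with the smallest node id.
#'
#' @param tree a [neuron_tree()] with at least 2 nodes.
#' @return Integer vector of node ids, root first.
#' @export
longest_root_leaf_path <- function(tree) {
  stopifnot(inherits(tree, "neuron_tree"))
  if (nrow(tree$nodes) < 2) stop("no path: tree has a single node")
  ix <- tree_index(tree)
  ix$nodes$id[.longest_path_idx(ix, ix$root)]
}

#' Decompose an axonal arbor into classified segments
#'
#' Recursively extracts the longest root-to-leaf path ("main branch") as a
#' segment and processes each sub-tree hanging off it in the same way. A
#' branch point is shared: it ends the parent segment and starts each child
#' segment, so every segment has at least two points and the union of
#' segments covers every edge exactly once. The first extracted segment is
#' `primary`; later segments with sub-trees hanging off them are
#' `collateral`; segments without sub-trees are `terminal`.
#'
#' @param tree a [neuron_tree()] with at least 2 nodes.
#' @return List of [segment_path()] objects; the first is the primary
#'   segment, and there is one segment per leaf of the tree.
#' @export
decompose_arbor <- function(tree) {
  stopifnot(inherits(tree, "neuron_tree"))
  if (nrow(tree$nodes) < 2) stop("no path: tree has a single node")
  ix <- tree_index(tree)
  xyz <- cbind(ix$nodes$x, ix$nodes$y, ix$nodes$z)
  segments <- list()

  recurse <- function(root_i, first_child, is_first) {
    path <- .longest_path_idx(ix, root_i, first_child)
    # sub-trees hanging off the path: off-path children of path nodes
    off <- list()
    for (k in seq_along(path)) {
      v <- path[k]
      kids <- ix$children[[v]]
      if (k == 1 && !is.null(first_child)) kids <- first_child
      nxt <- if (k < length(path)) path[k + 1] else -1L
      for (c in setdiff(kids, nxt)) off[[length(off) + 1]] <- c(v, c)
    }
    cls <- if (is_first) "primary" else if (length(off)) "collateral" else "terminal"
    segments[[length(segments) + 1]] <<- segment_path(
      xyz[path, , drop = FALSE], seg_class = cls, neuron_id = tree$source_name
    )
    for (vc in off) recurse(vc[1], vc[2], FALSE)
  }

  recurse(ix$root, NULL, TRUE)
  segments
}

#' Tabulate segments of one or more neurons
#'
#' @param segments list of [segment_path()] objects.
#' @return data.frame with columns `neuron_id`, `seg_class`, `n_points`, `L`.
#' @export
segment_table <- function(segments) {
  data.frame(
    neuron_id = vapply(segments, `[[`, "", "neuron_id"),
    seg_class = vapply(segments, `[[`, "", "seg_class"),
    n_points = vapply(segments, `[[`, 1L, "n_points"),
    L = vapply(segments, `[[`, 1, "L")
  )
}
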