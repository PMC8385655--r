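#' Construct a neuron tree
#'
#' A `neuron_tree` is a rooted tree of 3D trace nodes, the in-memory form of
#' an SWC reconstruction. Coordinates are in micrometres. The SWC structure
#' type code (column 2) is carried through unchanged but never interpreted.
#'
#' @param nodes data.frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`. Exactly one node must have `parent == -1` (the
#'   root); every other `parent` must be an existing `id`.
#' @param source_name identifier for the neuron (defaults to "").
#' @return An object of class `neuron_tree` with elements `nodes`,
#'   `root_id` and `source_name`.
#' @export
neuron_tree <- function(nodes, source_name = "") {
  required <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!is.data.frame(nodes) || !all(required %in% names(nodes))) {
    stop("`nodes` must be a data.frame with columns ", paste(required, collapse = ", "))
  }
  nodes <- nodes[, required]
  if (nrow(nodes) == 0) stop("structure error: tree has no nodes")
  if (anyDuplicated(nodes$id)) {
    stop("structure error: duplicated node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  }
  if (any(nodes$id <= 0)) stop("structure error: node ids must be positive")
  root <- which(nodes$parent == -1)
  if (length(root) != 1) {
    stop("structure error: tree must have exactly one root (parent == -1), found ",
         length(root))
  }
  pidx <- match(nodes$parent, nodes$id)
  dangling <- is.na(pidx) & nodes$parent != -1
  if (any(dangling)) {
    stop("structure error: parent id(s) not present in tree: ",
         paste(unique(nodes$parent[dangling]), collapse = ", "))
  }
  # connectivity / acyclicity: every node must reach the root
  depth <- rep(NA_integer_, nrow(nodes))
  depth[root] <- 0L
  for (i in seq_len(nrow(nodes))) {
    if (!is.na(depth[i])) next
    chain <- integer(0)
    j <- i
    while (is.na(depth[j])) {
      if (j %in% chain) stop("structure error: cycle detected at node id ", nodes$id[j])
      chain <- c(chain, j)
      j <- pidx[j]
    }
    depth[chain] <- depth[j] + rev(seq_along(chain))
  }
  structure(
    list(nodes = nodes, root_id = nodes$id[root], source_name = source_name),
    class = "neuron_tree"
  )
}

#' @export
print.neuron_tree <- function(x, ...) {
  cat("<neuron_tree> ", x$source_name, ": ", nrow(x$nodes), " nodes, root id ",
      x$root_id, "\n", sep = "")
  invisible(x)
}

n_leaves <- function(tree) {
  sum(!tree$nodes$id %in% tree$nodes$parent)
}

#' Read an SWC neuron reconstruction
#'
#' Parses the standard whitespace-delimited 7-column SWC format
#' (id, type, x, y, z, radius, parent). Lines starting with `#` and blank
#' lines are ignored; node order in the file need not be topological.
#'
#' @param path path to an SWC file.
#' @param source_name neuron identifier; defaults to the file name without
#'   extension.
#' @return A validated [neuron_tree()].
#' @export
read_swc <- function(path, source_name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0) stop("parse error: no data lines in ", path)
  fields <- strsplit(trimws(lines[idx]), "\\s+")
  bad_len <- vapply(fields, length, 1L) != 7L
  if (any(bad_len)) {
    stop("parse error in ", path, " at line ", idx[which(bad_len)[1]],
         ": expected 7 whitespace-separated columns")
  }
  m <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = 7, byrow = TRUE))
  bad_num <- rowSums(is.na(m)) > 0
  if (any(bad_num)) {
    stop("parse error in ", path, " at line ", idx[which(bad_num)[1]],
         ": non-numeric field")
  }
  nodes <- data.frame(
    id = as.integer(m[, 1]), type = as.integer(m[, 2]),
    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
    parent = as.integer(m[, 7])
  )
  if (is.null(source_name)) {
    source_name <- sub("\\.[^.]*$", "", basename(path))
  }
  neuron_tree(nodes, source_name = source_name)
}

# Node indices (into tree$nodes) in a topological order, parents first.
topological_order <- function(tree) {
  nodes <- tree$nodes
  children <- split(seq_len(nrow(nodes)), factor(nodes$parent, levels = nodes$id))
  root <- which(nodes$parent == -1)
  order <- integer(nrow(nodes))
  stack <- root
  k <- 0L
  while (length(stack)) {
    i <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    order[k] <- i
    kids <- children[[as.character(nodes$id[i])]]
    if (length(kids)) stack <- c(stack, rev(kids[order(nodes$id[kids])]))
  }
  order
}

#' Write a neuron tree to SWC
#'
#' Nodes are renumbered 1..n in a topological order (every parent precedes
#' its children); the root's parent is -1. Coordinates and radii are emitted
#' at full double precision so that a read/write round trip is bitwise
#' faithful.
#'
#' @param tree a [neuron_tree()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(tree, path) {
  stopifnot(inherits(tree, "neuron_tree"))
  nodes <- tree$nodes
  if (nrow(nodes) == 0) stop("cannot write an empty tree")
  ord <- topological_order(tree)
  new_id <- integer(nrow(nodes))
  new_id[ord] <- seq_along(ord)
  parent_new <- ifelse(nodes$parent == -1, -1L,
                       new_id[match(nodes$parent, nodes$id)])
  lines <- sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                   new_id, nodes$type, nodes$x, nodes$y, nodes$z,
                   nodes$radius, parent_new)
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
  on.exit(close(con))
  writeLines(c("# id type x y z radius parent", lines[order(new_id)]), con)
  invisible(path)
}

#' Randomly remove trace points from a neuron tree
#'
#' Each non-root node is removed independently with probability `p_remove`;
#' the children of a removed node are re-connected to its (surviving)
#' parent. This emulates annotators varying the spacing of trace points.
#' The root is never removed. Deterministic for a given seed.
#'
#' @param tree a [neuron_tree()].
#' @param p_remove removal probability in `[0, 1)`.
#' @param rng_seed integer seed; the caller's RNG state is left untouched.
#' @return A perturbed, validated [neuron_tree()].
#' @export
remove_random_nodes <- function(tree, p_remove, rng_seed = NULL) {
  stopifnot(inherits(tree, "neuron_tree"))
  if (!is.numeric(p_remove) || p_remove < 0 || p_remove >= 1) {
    stop("`p_remove` must be in [0, 1)")
  }
  nodes <- tree$nodes
  non_root <- nodes$parent != -1
  removed <- rep(FALSE, nrow(nodes))
  removed[non_root] <- with_seed(rng_seed,
                                 stats::runif(sum(non_root)) < p_remove)
  if (!any(removed)) {
    return(neuron_tree(nodes, source_name = tree$source_name))
  }
  # surviving ancestor of each node: walk up past removed nodes
  pidx <- match(nodes$parent, nodes$id)
  surv_parent <- function(i) {
    j <- pidx[i]
    while (!is.na(j) && removed[j]) j <- pidx[j]
    j
  }
  keep <- which(!removed)
  out <- nodes[keep, ]
  new_parent <- vapply(keep, function(i) {
    if (nodes$parent[i] == -1) return(-1L)
    as.integer(nodes$id[surv_parent(i)])
  }, 1L)
  out$parent <- new_parent
  neuron_tree(out, source_name = tree$source_name)
}
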