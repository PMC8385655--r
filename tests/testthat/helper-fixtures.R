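# Shared fixtures built in code.

# unbranched path along x with given inter-node spacing
path_tree <- function(n = 5, spacing = 1, id_offset = 0) {
  neuron_tree(data.frame(
    id = id_offset + seq_len(n), type = 2L,
    x = spacing * (seq_len(n) - 1), y = 0, z = 0, radius = 1,
    parent = c(-1L, id_offset + seq_len(n - 1))
  ), source_name = "path")
}

# Y-shaped tree: root -> A, then two limbs of given lengths along +/- y
y_tree <- function(len_b = 3, len_c = 5, step = 1) {
  nb <- len_b / step
  nc <- len_c / step
  nodes <- data.frame(
    id = 1:(2 + nb + nc), type = 2L, x = 0, y = 0, z = 0, radius = 1,
    parent = 0L
  )
  nodes$parent[1] <- -1L
  nodes$x[2] <- 1
  nodes$parent[2] <- 1L
  # limb B: ids 3..(2+nb), along +y from A
  for (k in seq_len(nb)) {
    i <- 2 + k
    nodes$x[i] <- 1
    nodes$y[i] <- k * step
    nodes$parent[i] <- if (k == 1) 2L else i - 1L
  }
  # limb C: ids (3+nb)..(2+nb+nc), along -y from A
  for (k in seq_len(nc)) {
    i <- 2 + nb + k
    nodes$x[i] <- 1
    nodes$y[i] <- -k * step
    nodes$parent[i] <- if (k == 1) 2L else i - 1L
  }
  neuron_tree(nodes, source_name = "ytree")
}

# helix sampled points as a segment_path
helix_segment <- function(r = 1, c = 1, length = 100, spacing = 0.5,
                          seg_class = "primary", neuron_id = "helix") {
  pts <- make_curve_points(curve_spec("helix", radius = r, pitch = c,
                                      length = length, point_spacing = spacing))
  segment_path(pts, seg_class, neuron_id)
}

random_rotation_fixture <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

apply_rigid <- function(tree, rot, shift) {
  xyz <- as.matrix(tree$nodes[, c("x", "y", "z")]) %*% t(rot)
  nodes <- tree$nodes
  nodes[, c("x", "y", "z")] <- sweep(xyz, 2, shift, `+`)
  neuron_tree(nodes, source_name = tree$source_name)
}
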