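#' Specify an analytic space curve
#'
#' Ground-truth curves for validating the spline/geometry pipeline:
#' a line has curvature and torsion 0; a circular arc of radius `r` has
#' curvature `1/r` and torsion 0; a helix `(r cos t, r sin t, c t)` has
#' constant curvature `r / (r^2 + c^2)` and torsion `c / (r^2 + c^2)`.
#'
#' @param kind `"line"`, `"arc"` or `"helix"`.
#' @param radius radius `r` in um (arc, helix).
#' @param pitch pitch parameter `c` in um per radian (helix).
#' @param length curve length in um (measured along the curve).
#' @param point_spacing arclength spacing of the sampled points, um.
#' @param origin 3-vector where the curve starts.
#' @param orientation 3 x 3 rotation matrix applied about the start point.
#' @return Object of class `curve_spec`.
#' @export
curve_spec <- function(kind = c("line", "arc", "helix"), radius = NA,
                       pitch = NA, length = 10, point_spacing = 0.5,
                       origin = c(0, 0, 0), orientation = diag(3)) {
  kind <- match.arg(kind)
  if (kind %in% c("arc", "helix") && (!is.finite(radius) || radius <= 0)) {
    stop("`radius` must be positive for arcs and helices")
  }
  if (kind == "helix" && !is.finite(pitch)) stop("`pitch` is required for a helix")
  structure(list(kind = kind, radius = radius, pitch = pitch, length = length,
                 point_spacing = point_spacing, origin = origin,
                 orientation = orientation),
            class = "curve_spec")
}

#' Analytic curvature and torsion magnitude of a curve spec
#'
#' @param spec a [curve_spec()].
#' @return Named vector `c(curvature = ..., torsion = ...)` in 1/um.
#' @export
analytic_geometry <- function(spec) {
  stopifnot(inherits(spec, "curve_spec"))
  switch(spec$kind,
    line = c(curvature = 0, torsion = 0),
    arc = c(curvature = 1 / spec$radius, torsion = 0),
    helix = {
      d <- spec$radius^2 + spec$pitch^2
      c(curvature = spec$radius / d, torsion = abs(spec$pitch) / d)
    }
  )
}

#' Sample points along an analytic curve
#'
#' Points are spaced `point_spacing` apart in arclength along the exact
#' parametric curve (helices are traversed at constant speed
#' `sqrt(r^2 + c^2)`, so consecutive chords are equal). The curve starts at
#' `origin` and `orientation` rotates it about the start.
#'
#' @param spec a [curve_spec()].
#' @return n x 3 matrix of coordinates, first row equal to `origin`.
#' @export
make_curve_points <- function(spec) {
  stopifnot(inherits(spec, "curve_spec"))
  if (spec$point_spacing <= 0) stop("point spacing must be positive")
  if (spec$point_spacing > spec$length) stop("point spacing exceeds curve length")
  s <- seq(0, spec$length, by = spec$point_spacing)
  pts <- switch(spec$kind,
    line = cbind(s, 0, 0),
    arc = {
      th <- s / spec$radius
      spec$radius * cbind(sin(th), 1 - cos(th), 0 * th)
    },
    helix = {
      speed <- sqrt(spec$radius^2 + spec$pitch^2)
      th <- s / speed
      p <- cbind(spec$radius * cos(th), spec$radius * sin(th), spec$pitch * th)
      sweep(p, 2, p[1, ])  # start at the origin of the frame
    }
  )
  pts <- pts %*% t(spec$orientation)
  sweep(pts, 2, spec$origin, `+`)
}

# append a curve's nodes to a node table, parenting the first new node to
# `attach_id`; returns list(nodes, ids of the appended curve points)
.append_curve <- function(nodes, pts, attach_id) {
  start <- if (nrow(nodes)) max(nodes$id) else 0L
  ids <- start + seq_len(nrow(pts) - 1)
  parent <- c(attach_id, ids[-length(ids)])
  rbind(nodes, data.frame(id = ids, type = 2L,
                          x = pts[-1, 1], y = pts[-1, 2], z = pts[-1, 3],
                          radius = 1, parent = parent))
}

#' Assemble an arbor specification into a neuron tree
#'
#' The trunk curve becomes the root-to-end backbone; each branch attaches
#' at the trunk (or parent-branch) point nearest the stated fraction of its
#' parent's points, sharing that point as the branch's first point.
#' Branches are given as lists `list(at = fraction, curve = curve_spec,
#' children = list(...))` and may nest. Optional isotropic Gaussian jitter
#' (standard deviation `jitter_sd`, um) is applied to all non-root nodes;
#' the default 0 keeps the ground-truth geometry exact.
#'
#' @param trunk a [curve_spec()] for the main branch.
#' @param branches list of branch specifications (possibly nested).
#' @param source_name neuron identifier.
#' @param jitter_sd coordinate noise standard deviation in um (default 0).
#' @param rng_seed seed for the jitter.
#' @return A [neuron_tree()].
#' @export
build_arbor <- function(trunk, branches = list(), source_name = "synthetic",
                        jitter_sd = 0, rng_seed = NULL) {
  trunk_pts <- make_curve_points(trunk)
  n0 <- nrow(trunk_pts)
  nodes <- data.frame(id = seq_len(n0), type = 2L,
                      x = trunk_pts[, 1], y = trunk_pts[, 2], z = trunk_pts[, 3],
                      radius = 1, parent = c(-1L, seq_len(n0 - 1)))

  add_branches <- function(nodes, branches, parent_ids, parent_pts) {
    for (br in branches) {
      if (is.null(br$at) || is.null(br$curve)) {
        stop("each branch needs `at` (attachment fraction) and `curve`")
      }
      k <- round(br$at * (nrow(parent_pts) - 1)) + 1
      attach_id <- parent_ids[k]
      attach_xyz <- parent_pts[k, ]
      spec <- br$curve
      spec$origin <- attach_xyz
      pts <- make_curve_points(spec)
      nodes <- .append_curve(nodes, pts, attach_id)
      new_n <- nrow(pts) - 1
      new_ids <- c(attach_id, nodes$id[(nrow(nodes) - new_n + 1):nrow(nodes)])
      if (length(br$children %||% list())) {
        nodes <- add_branches(nodes, br$children, new_ids, pts)
      }
    }
    nodes
  }
  nodes <- add_branches(nodes, branches, seq_len(n0), trunk_pts)

  if (jitter_sd > 0) {
    non_root <- nodes$parent != -1
    noise <- with_seed(rng_seed,
                       matrix(stats::rnorm(3 * sum(non_root), 0, jitter_sd), ncol = 3))
    nodes[non_root, c("x", "y", "z")] <- nodes[non_root, c("x", "y", "z")] + noise
  }
  neuron_tree(nodes, source_name = source_name)
}

#' Default class geometry for synthetic cohorts
#'
#' Per-class analytic curve families planting the ordering
#' curvature: collateral > terminal > primary and
#' torsion: collateral > primary > terminal:
#' primary trunk = gentle helix (r = 4, c = 4: curvature = torsion = 0.125),
#' collateral = tight helix (r = 1, c = 1: curvature = torsion = 0.5),
#' terminal = planar arc (r = 4: curvature = 0.25, torsion = 0).
#' Point spacing is 0.5 um so the chord-length parameter tracks arclength
#' closely on the tightest helix.
#'
#' @return Named list of [curve_spec()] (`primary`, `collateral`,
#'   `terminal`).
#' @export
default_class_geometry <- function() {
  list(
    primary = curve_spec("helix", radius = 4, pitch = 4, length = 100,
                         point_spacing = 0.5),
    collateral = curve_spec("helix", radius = 1, pitch = 1, length = 30,
                            point_spacing = 0.5),
    terminal = curve_spec("arc", radius = 4, length = 15, point_spacing = 0.5)
  )
}

# uniformly random rotation matrix (QR of a Gaussian matrix, sign-fixed)
.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a synthetic cohort of neurons
#'
#' Each neuron is a trunk (primary class geometry) carrying two branches
#' built from the collateral geometry — each with one terminal-geometry
#' child, so they classify as collateral — plus one terminal-geometry
#' branch directly on the trunk. Attachment fractions are kept at or below
#' 0.5 so the trunk is always the longest root-to-leaf path and the
#' decomposition is predictable. Branch orientations and small attachment
#' offsets are randomized per neuron (seeded).
#'
#' @param n_neurons cohort size.
#' @param class_geometry named list of [curve_spec()] per class; defaults to
#'   [default_class_geometry()].
#' @param rng_seed integer seed.
#' @return List of [neuron_tree()] named `neuron_001`, ...
#' @export
make_cohort <- function(n_neurons, class_geometry = default_class_geometry(),
                        rng_seed = 1) {
  stopifnot(n_neurons >= 1)
  with_seed(rng_seed, {
    lapply(seq_len(n_neurons), function(i) {
      orient <- function(spec) {
        spec$orientation <- .random_rotation()
        spec
      }
      coll <- class_geometry$collateral
      term <- class_geometry$terminal
      branch_coll <- function(at) {
        list(at = at, curve = orient(coll),
             children = list(list(at = 0.4, curve = orient(term))))
      }
      jit <- function(a) a + stats::runif(1, -0.03, 0.03)
      build_arbor(
        trunk = class_geometry$primary,
        branches = list(
          branch_coll(jit(0.2)),
          branch_coll(jit(0.45)),
          list(at = jit(0.33), curve = orient(term))
        ),
        source_name = sprintf("neuron_%03d", i)
      )
    })
  })
}

#' Write a synthetic cohort to SWC files with a manifest
#'
#' @param trees list of [neuron_tree()].
#' @param dir output directory (created if needed).
#' @param seed seed recorded in the manifest.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(trees, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(trees, function(tr) {
    f <- file.path(dir, paste0(tr$source_name, ".swc"))
    write_swc(tr, f)
    f
  }, "")
  manifest <- list(seed = seed, n_neurons = length(trees),
                   files = basename(files))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE)
  invisible(mpath)
}
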