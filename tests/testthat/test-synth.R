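test_that("analytic curve samplings have the stated geometry", {
  # line: 11 collinear points at spacing 1
  pts <- make_curve_points(curve_spec("line", length = 10, point_spacing = 1))
  expect_equal(nrow(pts), 11)
  expect_equal(pts[, 1], 0:10)
  expect_true(all(pts[, 2:3] == 0))
  # quarter circle of radius 2: all points on the circle to 1e-12
  arc <- curve_spec("arc", radius = 2, length = pi, point_spacing = 0.1)
  pa <- make_curve_points(arc)
  d <- sqrt(pa[, 1]^2 + (pa[, 2] - 2)^2)  # centre at (0, r, 0)
  expect_equal(d, rep(2, nrow(pa)), tolerance = 1e-12)
  # helix: constant-speed parameterization gives equal consecutive chords
  ph <- make_curve_points(curve_spec("helix", radius = 1, pitch = 1,
                                     length = 20, point_spacing = 0.5))
  chords <- sqrt(rowSums(diff(ph)^2))
  expect_equal(chords, rep(chords[1], length(chords)), tolerance = 1e-12)
  expect_error(make_curve_points(curve_spec("line", length = 1, point_spacing = 2)),
               "exceeds")
})

test_that("analytic_geometry returns the closed-form constants", {
  expect_equal(analytic_geometry(curve_spec("line", length = 1)),
               c(curvature = 0, torsion = 0))
  expect_equal(analytic_geometry(curve_spec("arc", radius = 2, length = 1)),
               c(curvature = 0.5, torsion = 0))
  expect_equal(analytic_geometry(curve_spec("helix", radius = 1, pitch = 1, length = 1)),
               c(curvature = 0.5, torsion = 0.5))
})

test_that("orientation and origin place curves without distorting them", {
  set.seed(14)
  rot <- random_rotation_fixture()
  spec <- curve_spec("helix", radius = 1, pitch = 1, length = 30,
                     point_spacing = 0.5, origin = c(5, -3, 2), orientation = rot)
  pts <- make_curve_points(spec)
  expect_equal(pts[1, ], c(5, -3, 2))
  cv <- fit_segment(segment_path(pts, "primary", "rot"))
  t_mid <- seq(5, 25, by = 1)
  expect_equal(mean(curvature(cv, t_mid)), 0.5, tolerance = 0.02)
})

test_that("trunk-only arbors decompose to a single primary segment", {
  tree <- build_arbor(curve_spec("line", length = 20, point_spacing = 1),
                      source_name = "trunk_only")
  segs <- decompose_arbor(tree)
  expect_length(segs, 1)
  expect_equal(segs[[1]]$seg_class, "primary")
  expect_equal(segs[[1]]$n_points, 21)
})

test_that("a trunk with one helix limb yields primary + terminal with known geometry", {
  tree <- build_arbor(
    trunk = curve_spec("line", length = 100, point_spacing = 1),
    branches = list(list(
      at = 0.3,
      curve = curve_spec("helix", radius = 1, pitch = 1, length = 20,
                         point_spacing = 0.5)
    )),
    source_name = "one_limb"
  )
  segs <- decompose_arbor(tree)
  classes <- vapply(segs, `[[`, "", "seg_class")
  expect_setequal(classes, c("primary", "terminal"))
  term <- segs[[which(classes == "terminal")]]
  g <- sample_geometry(fit_segment(term))
  expect_equal(mean(g$curvature), 0.5, tolerance = 0.05)
  expect_equal(mean(g$torsion_magnitude), 0.5, tolerance = 0.05)
})

test_that("arbor assembly is reproducible and jitter is seeded", {
  trunk <- curve_spec("line", length = 20, point_spacing = 1)
  a <- build_arbor(trunk, jitter_sd = 0)
  b <- build_arbor(trunk, jitter_sd = 0)
  expect_identical(a$nodes, b$nodes)
  j1 <- build_arbor(trunk, jitter_sd = 0.1, rng_seed = 5)
  j2 <- build_arbor(trunk, jitter_sd = 0.1, rng_seed = 5)
  j3 <- build_arbor(trunk, jitter_sd = 0.1, rng_seed = 6)
  expect_identical(j1$nodes, j2$nodes)
  expect_false(identical(j1$nodes, j3$nodes))
  # root is never jittered
  expect_equal(unlist(j1$nodes[1, c("x", "y", "z")]),
               unlist(a$nodes[1, c("x", "y", "z")]))
})

test_that("cohorts plant the intended class structure", {
  trees <- make_cohort(4, rng_seed = 123)
  expect_length(trees, 4)
  # deterministic given the seed
  trees2 <- make_cohort(4, rng_seed = 123)
  expect_identical(lapply(trees, `[[`, "nodes"), lapply(trees2, `[[`, "nodes"))
  for (tr in trees) {
    segs <- decompose_arbor(tr)
    classes <- vapply(segs, `[[`, "", "seg_class")
    expect_equal(sum(classes == "primary"), 1)
    expect_equal(sum(classes == "collateral"), 2)
    expect_equal(sum(classes == "terminal"), 3)
    # the trunk is the primary segment (longest root-leaf path by design)
    expect_equal(segs[[1]]$L, 100, tolerance = 1)
  }
})

test_that("per-class geometry is recovered within 2% on cohort neurons", {
  trees <- make_cohort(3, rng_seed = 7)
  geoms <- cohort_geometry(trees, run_config())
  cvs <- compute_class_values(geoms)
  truth_k <- c(primary = 0.125, collateral = 0.5, terminal = 0.25)
  truth_t <- c(primary = 0.125, collateral = 0.5, terminal = 0)
  for (cls in names(truth_k)) {
    got_k <- mean(cvs$curvature[cvs$seg_class == cls])
    expect_equal(got_k, unname(truth_k[cls]), tolerance = 0.02)
    got_t <- mean(cvs$torsion[cvs$seg_class == cls])
    if (truth_t[cls] > 0) {
      expect_equal(got_t, unname(truth_t[cls]), tolerance = 0.02)
    } else {
      expect_lt(got_t, 0.01)
    }
  }
})

test_that("cohort SWC files round-trip through the manifest", {
  dir <- withr::local_tempdir()
  trees <- make_cohort(2, rng_seed = 3)
  write_cohort(trees, dir, seed = 3)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$n_neurons, 2)
  expect_equal(manifest$seed, 3)
  back <- read_swc(file.path(dir, manifest$files[[1]]))
  expect_equal(nrow(back$nodes), nrow(trees[[1]]$nodes))
})
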