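# axongeom

Branching B-spline morphometry of axonal arbors.

Neuron reconstructions (SWC files) are usually analysed as piecewise-linear
trees, which makes their internal geometry — how a neurite bends and twists —
invisible: curvature and torsion are zero along line segments and undefined
at their joints. `axongeom` treats the trace points as samplings of
differentiable space curves. It:

- decomposes an arbor into **primary / collateral / terminal** segments by
  recursively extracting the longest root-to-leaf path (rigid-motion
  invariant, one segment per leaf);
- fits an **interpolating B-spline** through every trace point of each
  segment (degree 5 for >5 points, else 3/2/1; chord-length parameter
  values, zero smoothing), with the Cox–de Boor basis and its closed-form
  derivative recursion implemented directly;
- computes the **Frenet–Serret parameters** pointwise and in closed form,
  `kappa = ||x' x x''||` and `tau = <x' x x'', x'''> / ||x' x x''||^2`
  (torsion defined as 0 where curvature vanishes), sampled every 1 um;
- compares segment classes across neurons with **exact paired sign tests**
  (Binomial(n, 1/2) null, six tests, Bonferroni threshold 0.05/6 ≈ 0.0083),
  tabulates neurons over the **36 curvature/torsion class orderings**,
  analyses **autocorrelation** of curvature/torsion per lag against the 0.3
  moderate-correlation threshold, and repeats everything under a seeded
  **perturbation protocol** (20 dataset copies, each trace point removed
  with 10% probability);
- generates **synthetic arbors** from lines, arcs and helices with known
  analytic curvature/torsion, so the whole pipeline is validated without
  external data.

## Worked example

```r
library(axongeom)

# a 30-neuron synthetic cohort with planted class geometry:
# curvature C > T > P (0.5 / 0.25 / 0.125 um^-1),
# torsion   C > P > T (0.5 / 0.125 / ~0  um^-1)
trees <- make_cohort(30, rng_seed = 1)
res <- analyze_cohort(trees, run_config())
res$comparisons[, c("parameter", "class_a", "class_b", "direction", "p_value")]
#>    parameter    class_a    class_b           direction      p_value
#> 1  curvature    primary collateral  collateral>primary 9.313226e-10
#> 2  curvature collateral   terminal collateral>terminal 9.313226e-10
#> 3  curvature    primary   terminal    terminal>primary 9.313226e-10
#> 4    torsion    primary collateral  collateral>primary 9.313226e-10
#> 5    torsion collateral   terminal collateral>terminal 9.313226e-10
#> 6    torsion    primary   terminal    primary>terminal 9.313226e-10
```

All six one-sided sign tests recover the planted directions at
`p = 2^-30 = 9.3e-10`, far below the Bonferroni threshold 0.0083, and the
ordering table puts all 30 neurons in the (`C>T>P`, `C>P>T`) cell:

```r
max(res$ordering)
#> [1] 30
```

Single segments work the same way; a unit helix (analytic
curvature = torsion = 0.5 um^-1) is recovered within ~1%:

```r
pts <- make_curve_points(curve_spec("helix", radius = 1, pitch = 1,
                                    length = 100, point_spacing = 0.5))
g <- sample_geometry(fit_segment(segment_path(pts, "primary", "helix")))
c(mean(g$curvature), mean(g$torsion_magnitude))
#> [1] 0.5038847 0.5001905
```

For shell use, `inst/cli/axongeom.R` wraps the same functions as
`decompose`, `geometry`, `compare` and `synth` subcommands.

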