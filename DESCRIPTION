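Package: axongeom
Title: Branching B-Spline Morphometry of Axonal Arbors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Represents neuron reconstructions (SWC format) as branching
    interpolating B-splines and computes pointwise Frenet-Serret curvature
    and torsion in closed form. Arbors are decomposed into primary,
    collateral and terminal segments by recursive longest root-to-leaf path
    extraction; curvature and torsion are sampled at fixed spacing along
    each segment and compared between segment classes with exact paired
    sign tests, autocorrelation analyses, and a node-removal perturbation
    protocol. Includes a synthetic-arbor generator with analytically known
    geometry (lines, arcs, helices) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    splines,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
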