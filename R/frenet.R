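#' Pointwise curvature of a fitted curve
#'
#' Curvature measures deviation from straightness, in inverse micrometres.
#' The default (`variant = "chord"`) applies the unit-speed formula
#' \eqn{\kappa = \|x' \times x''\|} directly to derivatives taken with
#' respect to the chord-length parameter; for densely sampled traces the
#' chord-length parameter is close to arclength and the two agree. The
#' `"speed_invariant"` variant uses the parameterization-independent form
#' \eqn{\kappa = \|x' \times x''\| / \|x'\|^3}.
#'
#' @param curve a `bspline_curve` from [fit_segment()].
#' @param t parameter value(s) in `[0, L]`.
#' @param variant `"chord"` (default) or `"speed_invariant"`.
#' @return Non-negative curvature value(s) in 1/um.
#' @export
curvature <- function(curve, t, variant = c("chord", "speed_invariant")) {
  variant <- match.arg(variant)
  d1 <- evaluate_curve(curve, t, 1)
  d2 <- evaluate_curve(curve, t, 2)
  k <- row_norms(cross3(d1, d2))
  if (variant == "speed_invariant") k <- k / row_norms(d1)^3
  k
}

#' Pointwise (signed) torsion of a fitted curve
#'
#' Torsion measures deviation from planarity, in inverse micrometres:
#' \eqn{\tau = \langle x' \times x'', x''' \rangle / \|x' \times x''\|^2}.
#' Where curvature vanishes the formula is undefined and torsion is defined
#' to be zero; numerically, \eqn{\|x' \times x''\|} below `eps` triggers
#' this convention. The sign encodes handedness; downstream analyses use
#' the magnitude. The formula is invariant to the parameterization speed,
#' so there is no variant switch.
#'
#' @inheritParams curvature
#' @param eps vanishing-curvature threshold on \eqn{\|x' \times x''\|}.
#' @return Signed torsion value(s) in 1/um.
#' @export
torsion <- function(curve, t, eps = 1e-12) {
  d1 <- evaluate_curve(curve, t, 1)
  d2 <- evaluate_curve(curve, t, 2)
  d3 <- evaluate_curve(curve, t, 3)
  cr <- cross3(d1, d2)
  den <- rowSums(cr^2)
  tau <- ifelse(sqrt(den) < eps, 0, rowSums(cr * d3) / den)
  as.numeric(tau)
}

#' Sample curvature and torsion magnitude along a curve
#'
#' Evaluates curvature and torsion magnitude on the uniform grid
#' `t = 0, spacing, 2 spacing, ...` up to the curve length `L` (the
#' endpoint itself is included only when it falls on the grid). The default
#' 1 um spacing matches the precision of typical two-photon reconstructions.
#'
#' @inheritParams curvature
#' @param spacing sample spacing in micrometres (default 1).
#' @return Object of class `geometry_series`: list with `t` (sample
#'   positions), `curvature`, `torsion_magnitude`, `seg_class`, `neuron_id`.
#' @export
sample_geometry <- function(curve, spacing = 1,
                            variant = c("chord", "speed_invariant")) {
  variant <- match.arg(variant)
  stopifnot(inherits(curve, "bspline_curve"), spacing > 0)
  L <- curve$domain[2]
  t <- spacing * (0:floor(L / spacing + 1e-9))
  structure(
    list(t = t,
         curvature = curvature(curve, t, variant),
         torsion_magnitude = abs(torsion(curve, t)),
         seg_class = curve$seg_class,
         neuron_id = curve$neuron_id),
    class = "geometry_series"
  )
}

#' @export
print.geometry_series <- function(x, ...) {
  cat("<geometry_series> ", length(x$t), " samples, class ", x$seg_class,
      " (", x$neuron_id, ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.geometry_series <- function(x, ...) {
  data.frame(neuron_id = x$neuron_id, seg_class = x$seg_class, t_um = x$t,
             curvature = x$curvature, torsion_magnitude = x$torsion_magnitude)
}

#' Fit and sample every segment of a decomposed arbor
#'
#' Convenience wrapper: [fit_segment()] then [sample_geometry()] for each
#' segment.
#'
#' @param segments list of [segment_path()] objects.
#' @param spacing sample spacing in micrometres.
#' @param variant curvature formula variant, see [curvature()].
#' @param degree optional degree override passed to [fit_segment()].
#' @return List of `geometry_series`, one per segment.
#' @export
segment_geometry <- function(segments, spacing = 1,
                             variant = c("chord", "speed_invariant"),
                             degree = NULL) {
  variant <- match.arg(variant)
  lapply(segments, function(s) {
    sample_geometry(fit_segment(s, degree = degree), spacing = spacing,
                    variant = variant)
  })
}

#' Tabulate geometry series
#'
#' @param geoms list of `geometry_series`.
#' @return data.frame with columns `neuron_id`, `seg_class`, `t_um`,
#'   `curvature`, `torsion_magnitude`.
#' @export
geometry_table <- function(geoms) {
  do.call(rbind, lapply(geoms, as.data.frame))
}
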