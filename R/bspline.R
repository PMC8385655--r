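#' B-spline basis function (Cox-de Boor recursion)
#'
#' The j'th basis function for knot sequence `knots` and degree `p`,
#' evaluated at `x`:
#' \deqn{B_{j,p}(x) = \frac{x - \xi_j}{\xi_{j+p} - \xi_j} B_{j,p-1}(x) +
#'   \frac{\xi_{j+p+1} - x}{\xi_{j+p+1} - \xi_{j+1}} B_{j+1,p-1}(x)}
#' with the degree-0 base case being the indicator of
#' \eqn{[\xi_j, \xi_{j+1})}. Fractions with zero denominator have value
#' zero by convention. The last non-empty knot interval is treated as
#' closed on the right so the curve domain includes its endpoint.
#'
#' @param j basis index, 1-based: `1 <= j <= length(knots) - p - 1`.
#' @param p degree, non-negative integer.
#' @param knots non-decreasing knot sequence.
#' @param x evaluation point(s).
#' @return Basis value(s), same length as `x`.
#' @export
bspline_basis <- function(j, p, knots, x) {
  n <- length(knots) - p - 1
  if (p < 0 || j < 1 || j > n) {
    stop("index error: need 1 <= j <= length(knots) - p - 1 and p >= 0")
  }
  if (p == 0) {
    xmax <- knots[length(knots)]
    in_iv <- (x >= knots[j] & x < knots[j + 1]) |
      (x == xmax & knots[j] < knots[j + 1] & knots[j + 1] == xmax)
    return(as.numeric(in_iv))
  }
  d1 <- knots[j + p] - knots[j]
  d2 <- knots[j + p + 1] - knots[j + 1]
  a <- if (d1 > 0) (x - knots[j]) / d1 * bspline_basis(j, p - 1, knots, x) else 0
  b <- if (d2 > 0) (knots[j + p + 1] - x) / d2 * bspline_basis(j + 1, p - 1, knots, x) else 0
  a + b
}

#' Derivative of a B-spline basis function
#'
#' Closed-form derivative via the recursion
#' \deqn{\frac{d}{dx} B_{j,p}(x) = p \left(
#'   \frac{B_{j,p-1}(x)}{\xi_{j+p} - \xi_j} -
#'   \frac{B_{j+1,p-1}(x)}{\xi_{j+p+1} - \xi_{j+1}} \right)}
#' (zero-denominator fractions are zero), applied recursively for higher
#' orders. Derivatives of order greater than `p` are identically zero.
#'
#' @inheritParams bspline_basis
#' @param order derivative order, a positive integer.
#' @return Derivative value(s), same length as `x`.
#' @export
bspline_basis_deriv <- function(j, p, knots, x, order = 1) {
  n <- length(knots) - p - 1
  if (j < 1 || j > n) stop("index error: need 1 <= j <= length(knots) - p - 1")
  stopifnot(order >= 1)
  if (order > p) return(rep(0, length(x)))
  lower <- function(jj) {
    if (order == 1) bspline_basis(jj, p - 1, knots, x)
    else bspline_basis_deriv(jj, p - 1, knots, x, order - 1)
  }
  d1 <- knots[j + p] - knots[j]
  d2 <- knots[j + p + 1] - knots[j + 1]
  a <- if (d1 > 0) lower(j) / d1 else 0
  b <- if (d2 > 0) lower(j + 1) / d2 else 0
  p * (a - b)
}

# Vectorized design matrix: length(x) x (length(knots) - p - 1) matrix of
# degree-p basis values. Same recursion as bspline_basis, built iteratively.
.basis_matrix <- function(knots, p, x) {
  nk <- length(knots)
  xmax <- knots[nk]
  B <- matrix(0, length(x), nk - 1)
  for (i in seq_len(nk - 1)) {
    B[, i] <- (x >= knots[i] & x < knots[i + 1]) |
      (x == xmax & knots[i] < knots[i + 1] & knots[i + 1] == xmax)
  }
  if (p == 0) return(B)
  for (d in seq_len(p)) {
    ncol_new <- nk - d - 1
    Bn <- matrix(0, length(x), ncol_new)
    for (j in seq_len(ncol_new)) {
      d1 <- knots[j + d] - knots[j]
      d2 <- knots[j + d + 1] - knots[j + 1]
      v <- 0
      if (d1 > 0) v <- v + (x - knots[j]) / d1 * B[, j]
      if (d2 > 0) v <- v + (knots[j + d + 1] - x) / d2 * B[, j + 1]
      Bn[, j] <- v
    }
    B <- Bn
  }
  B
}

# Design matrix of order-r derivatives of the degree-p basis.
.deriv_matrix <- function(knots, p, x, order) {
  n <- length(knots) - p - 1
  if (order == 0) return(.basis_matrix(knots, p, x))
  if (order > p) return(matrix(0, length(x), n))
  M <- .deriv_matrix(knots, p - 1, x, order - 1)  # n + 1 columns
  D <- matrix(0, length(x), n)
  for (j in seq_len(n)) {
    d1 <- knots[j + p] - knots[j]
    d2 <- knots[j + p + 1] - knots[j + 1]
    v <- 0
    if (d1 > 0) v <- v + M[, j] / d1
    if (d2 > 0) v <- v - M[, j + 1] / d2
    D[, j] <- p * v
  }
  D
}

#' Spline degree for a trace-point count
#'
#' Degree 5 for more than 5 points (the minimal degree that makes the
#' interpolating spline thrice continuously differentiable), degree 3 for
#' 4-5 points, degree 2 for 3 points and degree 1 for 2 points. Even large
#' degrees (e.g. 4) are avoided, as they are not recommended for
#' interpolation.
#'
#' @param n number of trace points, `n >= 2`.
#' @return Integer degree in `{1, 2, 3, 5}`.
#' @export
select_degree <- function(n) {
  if (!is.numeric(n) || n < 2) stop("need at least 2 points")
  if (n > 5) 5L else if (n > 3) 3L else if (n == 3) 2L else 1L
}

#' Fit an interpolating B-spline to a segment
#'
#' Fits a 3D B-spline curve that passes exactly through every trace point
#' (zero smoothing). The parameter value of each trace point is its
#' cumulative chord length, so the curve is defined on `[0, L]` with `L`
#' the total chord length of the segment in micrometres. The degree comes
#' from [select_degree()] unless overridden. Boundary knots have
#' multiplicity `degree + 1` and interior knots are chord-parameter
#' averages, the standard interpolating-spline construction.
#'
#' @param seg a [segment_path()], or an n x 3 point matrix.
#' @param degree optional degree override (e.g. force 1 to emulate the
#'   piecewise-linear representation).
#' @return Object of class `bspline_curve` with fields `degree`, `knots`,
#'   `coefs` (n x 3), `domain`, `params`, and the segment's `seg_class` /
#'   `neuron_id` when available.
#' @export
fit_segment <- function(seg, degree = NULL) {
  if (inherits(seg, "segment_path")) {
    points <- seg$points
    seg_class <- seg$seg_class
    neuron_id <- seg$neuron_id
  } else {
    points <- as.matrix(seg)
    seg_class <- NA_character_
    neuron_id <- ""
  }
  m <- nrow(points)
  if (m < 2) stop("degenerate segment: fewer than 2 points")
  u <- cum_chord(points)
  if (any(diff(u) == 0)) stop("degenerate segment: coincident consecutive points")
  p <- if (is.null(degree)) select_degree(m) else as.integer(degree)
  if (p < 1 || p >= m) stop("degree must satisfy 1 <= degree < n_points")
  # clamped knots; interior knots by de Boor averaging (Schoenberg-Whitney)
  n_int <- m - p - 1
  interior <- if (n_int > 0) {
    vapply(seq_len(n_int), function(j) mean(u[(j + 1):(j + p)]), 1)
  } else numeric(0)
  knots <- c(rep(u[1], p + 1), interior, rep(u[m], p + 1))
  A <- .basis_matrix(knots, p, u)
  coefs <- solve(A, points)
  structure(
    list(degree = p, knots = knots, coefs = coefs, domain = c(0, u[m]),
         params = u, seg_class = seg_class, neuron_id = neuron_id),
    class = "bspline_curve"
  )
}

#' @export
print.bspline_curve <- function(x, ...) {
  cat("<bspline_curve> degree ", x$degree, ", ", nrow(x$coefs),
      " coefficients, domain [0, ", format(x$domain[2]), "] um\n", sep = "")
  invisible(x)
}

#' Evaluate a B-spline curve or its derivatives
#'
#' Derivatives are computed in closed form (no finite differencing) with
#' respect to the chord-length parameter.
#'
#' @param curve a `bspline_curve` from [fit_segment()].
#' @param t parameter value(s) in `[0, L]`; no extrapolation.
#' @param order 0 for position, 1-3 for derivatives.
#' @return length(t) x 3 matrix of positions or derivative vectors.
#' @export
evaluate_curve <- function(curve, t, order = 0) {
  stopifnot(inherits(curve, "bspline_curve"), order %in% 0:3)
  lo <- curve$domain[1]
  hi <- curve$domain[2]
  tol <- 1e-8 * max(1, hi)
  if (any(t < lo - tol | t > hi + tol)) {
    stop("domain error: parameter outside [0, ", format(hi), "]")
  }
  t <- pmin(pmax(t, lo), hi)
  D <- .deriv_matrix(curve$knots, curve$degree, t, order)
  D %*% curve$coefs
}
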