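# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Row-wise cross product of two n x 3 matrices.
cross3 <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

row_norms <- function(m) sqrt(rowSums(m^2))

# Cumulative chord length of an n x 3 point matrix: c(0, d1, d1+d2, ...).
cum_chord <- function(points) {
  if (nrow(points) < 2) return(0)
  d <- sqrt(rowSums(diff(points)^2))
  c(0, cumsum(d))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
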