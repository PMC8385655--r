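#' Normalized autocorrelation of a series
#'
#' \eqn{r(k) = \sum_t (x_t - \bar x)(x_{t+k} - \bar x) / \sum_t (x_t - \bar x)^2},
#' so `r(0) = 1`. Lag `k` is reported only when the series has at least
#' `k + 2` samples. A constant (zero-variance) series has no defined
#' autocorrelation and is flagged as excluded rather than propagating NaN.
#'
#' @param x numeric series (e.g. curvature sampled every 1 um), length >= 2.
#' @param max_lag maximum lag to compute.
#' @return List with `lags`, `r` (autocorrelation per lag) and `excluded`
#'   (TRUE for a zero-variance series, in which case `r` is empty).
#' @export
autocorrelation <- function(x, max_lag) {
  n <- length(x)
  if (n < 2) stop("series must have at least 2 samples")
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) {
    return(list(lags = integer(0), r = numeric(0), excluded = TRUE))
  }
  lags <- 0:min(max_lag, n - 2)
  r <- vapply(lags, function(k) {
    sum(xc[seq_len(n - k)] * xc[seq_len(n - k) + k]) / denom
  }, 1)
  list(lags = lags, r = r, excluded = FALSE)
}

#' Autocorrelation analysis across segments
#'
#' Computes the autocorrelation function of curvature or torsion magnitude
#' for every segment, then per lag tests whether the mean autocorrelation
#' across segments exceeds `threshold` (default 0.3, the conventional
#' boundary of a "moderate" correlation) with a one-sided one-sample
#' t-test. No correction is applied across lags; each lag is tested at
#' `alpha`. Zero-variance segments are excluded; a lag with fewer than two
#' contributing segments, or zero variance across segments, is recorded
#' with `p_value = NA`.
#'
#' @param geoms list of `geometry_series` (see [segment_geometry()]).
#' @param parameter `"curvature"` or `"torsion"`.
#' @param max_lag maximum lag in micrometres (grid units of the sampling).
#' @param threshold autocorrelation effect size under the null (default 0.3).
#' @param alpha per-lag significance level (default 0.05).
#' @return Object of class `autocorr_result`: data.frame with columns
#'   `lag`, `mean_autocorr`, `sd_autocorr`, `n_segments`, `p_value`,
#'   `significant`.
#' @export
autocorr_analysis <- function(geoms, parameter = c("curvature", "torsion"),
                              max_lag = 10, threshold = 0.3, alpha = 0.05) {
  parameter <- match.arg(parameter)
  field <- if (parameter == "curvature") "curvature" else "torsion_magnitude"
  acs <- lapply(geoms, function(g) {
    x <- g[[field]]
    if (length(x) < 2) return(NULL)
    a <- autocorrelation(x, max_lag)
    if (a$excluded) NULL else a
  })
  acs <- acs[!vapply(acs, is.null, TRUE)]
  out <- lapply(0:max_lag, function(k) {
    vals <- unlist(lapply(acs, function(a) a$r[match(k, a$lags)]))
    vals <- vals[!is.na(vals)]
    n <- length(vals)
    if (n == 0) {
      return(data.frame(lag = k, mean_autocorr = NA_real_, sd_autocorr = NA_real_,
                        n_segments = 0L, p_value = NA_real_, significant = NA))
    }
    m <- mean(vals)
    s <- stats::sd(vals)
    p <- if (n >= 2 && s > 0) {
      stats::t.test(vals, mu = threshold, alternative = "greater")$p.value
    } else NA_real_
    data.frame(lag = k, mean_autocorr = m, sd_autocorr = ifelse(n >= 2, s, NA_real_),
               n_segments = n, p_value = p,
               significant = if (is.na(p)) NA else p < alpha)
  })
  res <- do.call(rbind, out)
  class(res) <- c("autocorr_result", "data.frame")
  attr(res, "parameter") <- parameter
  attr(res, "threshold") <- threshold
  attr(res, "alpha") <- alpha
  res
}

#' Mean curvature or torsion magnitude of one segment
#'
#' @param geom a `geometry_series`.
#' @param parameter `"curvature"` or `"torsion"`.
#' @return Arithmetic mean of the sampled values.
#' @export
segment_mean <- function(geom, parameter = c("curvature", "torsion")) {
  parameter <- match.arg(parameter)
  x <- if (parameter == "curvature") geom$curvature else geom$torsion_magnitude
  if (length(x) == 0) stop("empty geometry series")
  mean(x)
}

#' Per-neuron class values of curvature and torsion
#'
#' For each neuron and segment class, summarizes the class by the
#' unweighted mean of its segment means (`pooling = "segment_mean"`, the
#' default) or by pooling all samples across the class's segments
#' (`pooling = "length_weighted"`, which weights segments by their sample
#' counts). Neurons lacking a class get `NA` for it.
#'
#' @param geoms list of `geometry_series` across neurons.
#' @param pooling `"segment_mean"` or `"length_weighted"`.
#' @return data.frame with one row per neuron x class:
#'   `neuron_id`, `seg_class`, `curvature`, `torsion`.
#' @export
compute_class_values <- function(geoms,
                                 pooling = c("segment_mean", "length_weighted")) {
  pooling <- match.arg(pooling)
  df <- data.frame(
    neuron_id = vapply(geoms, `[[`, "", "neuron_id"),
    seg_class = vapply(geoms, `[[`, "", "seg_class"),
    curvature = vapply(geoms, segment_mean, 1, parameter = "curvature"),
    torsion = vapply(geoms, segment_mean, 1, parameter = "torsion"),
    n_samples = vapply(geoms, function(g) length(g$t), 1L)
  )
  agg <- function(v, w) {
    if (pooling == "segment_mean") mean(v) else sum(v * w) / sum(w)
  }
  res <- do.call(rbind, lapply(split(df, df[c("seg_class", "neuron_id")], drop = TRUE),
    function(d) data.frame(
      neuron_id = d$neuron_id[1], seg_class = d$seg_class[1],
      curvature = agg(d$curvature, d$n_samples),
      torsion = agg(d$torsion, d$n_samples)
    )))
  rownames(res) <- NULL
  res
}

#' Class value of a single neuron
#'
#' @param geoms list of `geometry_series` for one neuron.
#' @param seg_class segment class to summarize.
#' @param parameter `"curvature"` or `"torsion"`.
#' @inheritParams compute_class_values
#' @return The class value, or `NA` if the neuron has no segment of that
#'   class.
#' @export
neuron_class_value <- function(geoms, seg_class, parameter = c("curvature", "torsion"),
                               pooling = c("segment_mean", "length_weighted")) {
  parameter <- match.arg(parameter)
  pooling <- match.arg(pooling)
  sel <- geoms[vapply(geoms, `[[`, "", "seg_class") == seg_class]
  if (length(sel) == 0) return(NA_real_)
  means <- vapply(sel, segment_mean, 1, parameter = parameter)
  if (pooling == "segment_mean") return(mean(means))
  w <- vapply(sel, function(g) length(g$t), 1L)
  sum(means * w) / sum(w)
}

#' Exact paired sign test
#'
#' Tests H0: Pr[X > Y] = 0.5 against a one-sided alternative. The statistic
#' is the number of pairs with `x > y`; ties are discarded and the null
#' distribution is Binomial(n, 1/2), computed exactly (no normal
#' approximation). Also reports the two-sided p-value (doubled minimal
#' tail, capped at 1), which is the appropriate level when the test
#' direction was chosen from the same data.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param direction `"greater"` tests Pr[X > Y] > 0.5, `"less"` the reverse.
#' @return List with `n_pos`, `n_neg`, `n_tie`, `n_effective`, `direction`,
#'   `p_value` (one-sided) and `p_two_sided`.
#' @export
sign_test <- function(x, y, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n_pos <- sum(x > y)
  n_neg <- sum(x < y)
  n_tie <- sum(x == y)
  n <- n_pos + n_neg
  if (n == 0) stop("no informative pairs (all tied or missing)")
  k <- if (direction == "greater") n_pos else n_neg
  p <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  p2 <- min(1, 2 * stats::pbinom(max(n_pos, n_neg) - 1, n, 0.5, lower.tail = FALSE))
  list(n_pos = n_pos, n_neg = n_neg, n_tie = n_tie, n_effective = n,
       direction = direction, p_value = p, p_two_sided = p2)
}

.class_pairs <- rbind(c("primary", "collateral"),
                      c("collateral", "terminal"),
                      c("primary", "terminal"))

#' Six paired class comparisons with Bonferroni control
#'
#' Runs one-sided exact sign tests for curvature and torsion magnitude over
#' the three class pairs (primary vs collateral, collateral vs terminal,
#' primary vs terminal): six tests, so the family-wise level `alpha` gives
#' the per-test threshold `alpha / 6` (0.0083 at the default 0.05). For
#' each test the direction is the empirical majority direction; the
#' reported one-sided `p_value` is conditional on that choice, so the
#' `significant` flag is gated on the direction-selection-adjusted p-value
#' (`p_adjusted`, the exact two-sided p), which keeps the family-wise
#' type-I error controlled.
#'
#' @param class_values data.frame from [compute_class_values()].
#' @param alpha family-wise significance level (default 0.05).
#' @return Object of class `comparison_result`: data.frame with columns
#'   `parameter`, `class_a`, `class_b`, `n_pos`, `n_neg`, `n_tie`,
#'   `direction` (e.g. `"collateral>primary"`), `p_value`, `p_adjusted`,
#'   `threshold`, `significant`.
#' @export
run_class_comparisons <- function(class_values, alpha = 0.05) {
  n_tests <- 6
  thr <- alpha / n_tests
  wide <- split(class_values, class_values$neuron_id)
  get_vals <- function(parameter, cls) {
    vapply(wide, function(d) {
      v <- d[[parameter]][d$seg_class == cls]
      if (length(v) == 1) v else NA_real_
    }, 1)
  }
  rows <- list()
  for (parameter in c("curvature", "torsion")) {
    for (q in seq_len(nrow(.class_pairs))) {
      a <- .class_pairs[q, 1]; b <- .class_pairs[q, 2]
      x <- get_vals(parameter, a)
      y <- get_vals(parameter, b)
      ok <- !is.na(x) & !is.na(y)
      dir <- if (sum(x[ok] > y[ok]) >= sum(x[ok] < y[ok])) "greater" else "less"
      st <- sign_test(x[ok], y[ok], direction = dir)
      rows[[length(rows) + 1]] <- data.frame(
        parameter = parameter, class_a = a, class_b = b,
        n_pos = st$n_pos, n_neg = st$n_neg, n_tie = st$n_tie,
        direction = if (dir == "greater") paste0(a, ">", b) else paste0(b, ">", a),
        p_value = st$p_value, p_adjusted = st$p_two_sided,
        threshold = thr, significant = st$p_two_sided < thr
      )
    }
  }
  res <- do.call(rbind, rows)
  class(res) <- c("comparison_result", "data.frame")
  attr(res, "alpha") <- alpha
  res
}

.perm3 <- function() {
  p <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  lab <- c(primary = "P", collateral = "C", terminal = "T")
  classes <- c("primary", "collateral", "terminal")
  list(perm = p,
       names = apply(p, 1, function(o) paste(lab[classes[o]], collapse = ">")))
}

#' Neuron counts over the 36 curvature/torsion class orderings
#'
#' For every neuron with all three segment classes and strict orderings of
#' its class values, identifies the ordering (a permutation of primary,
#' collateral, terminal) of curvature and of torsion, and counts neurons in
#' the resulting 6 x 6 table. Neurons missing a class or with exact ties
#' are excluded (strict total orders are required).
#'
#' @param class_values data.frame from [compute_class_values()].
#' @return Object of class `ordering_table`: a 6 x 6 integer matrix, rows
#'   indexed by the curvature ordering and columns by the torsion ordering
#'   (labels like `"C>T>P"`), with attribute `n_excluded`.
#' @export
ordering_counts <- function(class_values) {
  pp <- .perm3()
  classes <- c("primary", "collateral", "terminal")
  counts <- matrix(0L, 6, 6, dimnames = list(curvature = pp$names,
                                             torsion = pp$names))
  excluded <- 0L
  for (d in split(class_values, class_values$neuron_id)) {
    v_k <- d$curvature[match(classes, d$seg_class)]
    v_t <- d$torsion[match(classes, d$seg_class)]
    strict <- function(v) !anyNA(v) && length(unique(v)) == 3
    if (!strict(v_k) || !strict(v_t)) {
      excluded <- excluded + 1L
      next
    }
    ri <- function(v) which(apply(pp$perm, 1, function(o) all(diff(v[o]) < 0)))
    counts[ri(v_k), ri(v_t)] <- counts[ri(v_k), ri(v_t)] + 1L
  }
  structure(counts, class = c("ordering_table", "matrix"),
            n_excluded = excluded)
}

#' Perturbation robustness experiment
#'
#' Replicates the class-comparison analysis on copies of the dataset in
#' which every non-root trace point has been removed with probability
#' `p_remove` (children re-connected to the surviving parent). Replicate
#' `r` uses seed `base_seed + r`, so the experiment is exactly
#' reproducible.
#'
#' @param trees list of [neuron_tree()] objects.
#' @param p_remove per-node removal probability (default 0.1).
#' @param replicates number of perturbed copies of the dataset (default 20).
#' @param base_seed integer seed base.
#' @param config a [run_config()]; controls spacing, curvature variant,
#'   pooling and alpha.
#' @return List of `comparison_result` data.frames, one per replicate.
#' @export
perturbation_experiment <- function(trees, p_remove = 0.1, replicates = 20,
                                    base_seed = 1, config = run_config()) {
  lapply(seq_len(replicates), function(r) {
    perturbed <- lapply(trees, remove_random_nodes, p_remove = p_remove,
                        rng_seed = base_seed + r)
    geoms <- cohort_geometry(perturbed, config)
    run_class_comparisons(
      compute_class_values(geoms, pooling = config$pooling),
      alpha = config$alpha
    )
  })
}
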