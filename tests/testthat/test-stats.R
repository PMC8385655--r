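test_that("autocorrelation normalizes to 1 at lag 0 and matches hand values", {
  x <- c(2, 4, 1, 7, 3, 5)
  a <- autocorrelation(x, 3)
  expect_equal(a$r[a$lags == 0], 1)
  # alternating series of length 20: r(1) = -19/20
  alt <- rep(c(1, -1), 10)
  expect_equal(autocorrelation(alt, 1)$r[2], -0.95)
  # constant series is excluded, not NaN
  a0 <- autocorrelation(rep(3, 10), 5)
  expect_true(a0$excluded)
  expect_length(a0$r, 0)
})

test_that("autocorrelation matches a brute-force double loop", {
  brute <- function(x, max_lag) {
    n <- length(x)
    xb <- mean(x)
    den <- sum((x - xb)^2)
    vapply(0:min(max_lag, n - 2), function(k) {
      s <- 0
      for (t in seq_len(n - k)) s <- s + (x[t] - xb) * (x[t + k] - xb)
      s / den
    }, 1)
  }
  set.seed(99)
  for (rep in 1:10) {
    x <- rnorm(sample(5:60, 1))
    a <- autocorrelation(x, 12)
    expect_equal(a$r, brute(x, 12), tolerance = 1e-12)
  }
  # cross-check against stats::acf on one series
  x <- rnorm(50)
  expect_equal(autocorrelation(x, 10)$r,
               as.numeric(stats::acf(x, lag.max = 10, plot = FALSE,
                                     demean = TRUE)$acf),
               tolerance = 1e-12)
})

test_that("lag availability requires k + 2 samples", {
  a <- autocorrelation(rnorm(5), 10)
  expect_equal(max(a$lags), 3)
})

test_that("the per-lag t-test reproduces the closed-form example", {
  # r-values {0.4, 0.5, 0.6} vs 0.3: t = 3.464, df = 2, one-sided p = 0.0371
  p <- stats::t.test(c(0.4, 0.5, 0.6), mu = 0.3, alternative = "greater")$p.value
  t_stat <- (0.5 - 0.3) / (sd(c(0.4, 0.5, 0.6)) / sqrt(3))
  expect_equal(t_stat, 3.4641, tolerance = 1e-4)
  expect_equal(p, stats::pt(t_stat, df = 2, lower.tail = FALSE))
  expect_equal(p, 0.03709, tolerance = 1e-3)
})

test_that("autocorr_analysis aggregates per lag and flags degenerate lags", {
  set.seed(8)
  mk <- function(x, cls = "primary", id = "n1") {
    structure(list(t = seq_along(x) - 1, curvature = x,
                   torsion_magnitude = abs(x), seg_class = cls, neuron_id = id),
              class = "geometry_series")
  }
  geoms <- lapply(1:6, function(i) mk(rnorm(30, 1, 0.2), id = paste0("n", i)))
  res <- autocorr_analysis(geoms, "curvature", max_lag = 5)
  expect_s3_class(res, "autocorr_result")
  expect_equal(res$mean_autocorr[res$lag == 0], 1)
  expect_true(all(diff(res$n_segments) <= 0))
  expect_equal(res$n_segments, rep(6L, 6))
  # constant series are excluded from the averaging
  res2 <- autocorr_analysis(c(geoms, list(mk(rep(2, 30)))), "curvature", max_lag = 5)
  expect_equal(res2$n_segments, rep(6L, 6))
  # sd = 0 across segments -> test undefined, recorded as absent
  same <- lapply(1:3, function(i) mk(rep(c(1, -1), 10), id = paste0("s", i)))
  res3 <- autocorr_analysis(same, "curvature", max_lag = 2)
  expect_true(is.na(res3$p_value[res3$lag == 1]))
  # strongly positive autocorrelation vs threshold 0: p < 0.05
  slow <- lapply(1:6, function(i) mk(cumsum(rnorm(40)) + 10, id = paste0("w", i)))
  res4 <- autocorr_analysis(slow, "curvature", max_lag = 1, threshold = 0)
  expect_lt(res4$p_value[res4$lag == 1], 0.05)
})

test_that("segment and class means follow the stated pooling", {
  g1 <- structure(list(t = 0:4, curvature = c(0.1, 0.1, 0.1, 0.1, 0.1),
                       torsion_magnitude = rep(0.2, 5),
                       seg_class = "terminal", neuron_id = "n1"),
                  class = "geometry_series")
  g2 <- structure(list(t = 0:14, curvature = rep(0.3, 15),
                       torsion_magnitude = rep(0.4, 15),
                       seg_class = "terminal", neuron_id = "n1"),
                  class = "geometry_series")
  expect_equal(segment_mean(g1, "curvature"), 0.1)
  expect_equal(segment_mean(g1, "torsion"), 0.2)
  # unweighted mean of segment means
  expect_equal(neuron_class_value(list(g1, g2), "terminal", "curvature"), 0.2)
  # length-weighted pooling weights by sample count
  expect_equal(neuron_class_value(list(g1, g2), "terminal", "curvature",
                                  pooling = "length_weighted"),
               (5 * 0.1 + 15 * 0.3) / 20)
  # missing class is absent
  expect_true(is.na(neuron_class_value(list(g1, g2), "collateral", "curvature")))
  cv <- compute_class_values(list(g1, g2))
  expect_equal(nrow(cv), 1)
  expect_equal(cv$curvature, 0.2)
})

test_that("the exact sign test matches hand-computed binomial tails", {
  x <- c(rep(1, 8), rep(0, 2))
  y <- rep(0.5, 10)
  st <- sign_test(x, y, "greater")
  expect_equal(st$n_pos, 8)
  expect_equal(st$p_value, 56 / 1024)
  # k = n gives 2^-n
  st2 <- sign_test(1:12 + 1, 1:12, "greater")
  expect_equal(st2$p_value, 2^-12)
  # ties are removed
  st3 <- sign_test(c(1, 2, 3, 5), c(1, 1, 1, 9), "greater")
  expect_equal(st3$n_tie, 1)
  expect_equal(st3$n_effective, 3)
  expect_error(sign_test(c(1, 2), c(1, 2)), "no informative pairs")
})

test_that("sign-test p-values match exhaustive enumeration of sign patterns", {
  # enumeration oracle: all 2^n equally likely sign patterns under H0
  enum_p <- function(n, k) {
    counts <- vapply(0:n, function(j) choose(n, j), 1)
    sum(counts[(k + 1):(n + 1)]) / 2^n
  }
  for (n in c(3, 5, 8)) {
    patterns <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    for (k in 0:n) {
      x <- c(rep(1, k), rep(-1, n - k))
      st <- sign_test(x, rep(0, n), "greater")
      expect_equal(st$p_value, enum_p(n, k))
      expect_equal(st$p_value, mean(rowSums(patterns) >= k))
    }
  }
})

test_that("six class comparisons use the Bonferroni threshold and majority direction", {
  set.seed(31)
  n <- 20
  cvs <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(
      neuron_id = sprintf("n%02d", i),
      seg_class = c("primary", "collateral", "terminal"),
      curvature = c(0.1, 0.5, 0.25) + runif(3, 0, 0.02),
      torsion = c(0.12, 0.5, 0.01) + runif(3, 0, 0.002)
    )
  }))
  res <- run_class_comparisons(cvs)
  expect_equal(nrow(res), 6)
  expect_equal(unique(res$threshold), 0.05 / 6)
  expect_equal(round(unique(res$threshold), 4), 0.0083)
  expect_true(all(res$significant))
  expect_equal(res$p_value, rep(2^-n, 6))
  k_dir <- res$direction[res$parameter == "curvature"]
  expect_equal(k_dir, c("collateral>primary", "collateral>terminal",
                        "terminal>primary"))
  t_dir <- res$direction[res$parameter == "torsion"]
  expect_equal(t_dir, c("collateral>primary", "collateral>terminal",
                        "primary>terminal"))
})

test_that("neurons missing a class drop out of the affected pairs only", {
  cvs <- data.frame(
    neuron_id = c("a", "a", "a", "b", "b"),
    seg_class = c("primary", "collateral", "terminal", "primary", "terminal"),
    curvature = c(0.1, 0.5, 0.3, 0.2, 0.4),
    torsion = c(0.1, 0.5, 0.05, 0.2, 0.1)
  )
  res <- run_class_comparisons(cvs)
  pc <- res[res$parameter == "curvature" & res$class_b == "collateral", ]
  pt <- res[res$parameter == "curvature" & res$class_a == "primary" &
              res$class_b == "terminal", ]
  expect_equal(pc$n_pos + pc$n_neg + pc$n_tie, 1)
  expect_equal(pt$n_pos + pt$n_neg + pt$n_tie, 2)
})

test_that("family-wise type-I error is controlled under label shuffling", {
  set.seed(2024)
  n <- 30
  n_sims <- 200
  base <- expand.grid(neuron_id = sprintf("n%02d", seq_len(n)),
                      seg_class = c("primary", "collateral", "terminal"),
                      stringsAsFactors = FALSE)
  rejections <- vapply(seq_len(n_sims), function(s) {
    vals_k <- matrix(rnorm(3 * n, 0.3, 0.1), n, 3)
    vals_t <- matrix(rnorm(3 * n, 0.2, 0.1), n, 3)
    # shuffle class labels within each neuron (values are exchangeable anyway)
    cvs <- do.call(rbind, lapply(seq_len(n), function(i) {
      o <- sample(3)
      data.frame(neuron_id = sprintf("n%02d", i),
                 seg_class = c("primary", "collateral", "terminal"),
                 curvature = vals_k[i, o], torsion = vals_t[i, o])
    }))
    any(run_class_comparisons(cvs)$significant)
  }, TRUE)
  rate <- mean(rejections)
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sims))
})

test_that("ordering counts index the 36 orderings and exclude ties", {
  cvs <- data.frame(
    neuron_id = "a", seg_class = c("primary", "collateral", "terminal"),
    curvature = c(0.1, 0.5, 0.3),   # C > T > P
    torsion = c(0.3, 0.5, 0.1)      # C > P > T
  )
  tab <- ordering_counts(cvs)
  expect_equal(sum(tab), 1)
  expect_equal(tab["C>T>P", "C>P>T"], 1L)
  # tie in torsion -> excluded
  cvs2 <- cvs
  cvs2$torsion <- c(0.5, 0.5, 0.1)
  tab2 <- ordering_counts(cvs2)
  expect_equal(sum(tab2), 0)
  expect_equal(attr(tab2, "n_excluded"), 1L)
  # missing class -> excluded; total + excluded = cohort size
  cvs3 <- rbind(cvs, data.frame(neuron_id = "b",
                                seg_class = c("primary", "terminal"),
                                curvature = c(0.1, 0.2), torsion = c(0.1, 0.2)))
  tab3 <- ordering_counts(cvs3)
  expect_equal(sum(tab3) + attr(tab3, "n_excluded"), 2)
})
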