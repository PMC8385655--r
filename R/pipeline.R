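#' Analysis run configuration
#'
#' Bundles every tunable of the end-to-end analysis. The defaults are the
#' study settings: 1 um sampling, autocorrelation threshold 0.3, family-wise
#' alpha 0.05 over six tests, curvature formulas applied to chord-length
#' derivatives, unweighted segment-mean pooling, and a perturbation protocol
#' of 20 replicates at 10% node removal.
#'
#' @param spacing geometry sample spacing, um.
#' @param max_lag maximum autocorrelation lag, grid units (um).
#' @param threshold autocorrelation null threshold.
#' @param alpha family-wise significance level.
#' @param variant curvature formula variant, see [curvature()].
#' @param pooling per-neuron class pooling, see [compute_class_values()].
#' @param p_remove perturbation removal probability.
#' @param replicates perturbation replicates.
#' @param base_seed base seed; all randomness in a run flows from it.
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(spacing = 1, max_lag = 10, threshold = 0.3,
                       alpha = 0.05, variant = "chord",
                       pooling = "segment_mean", p_remove = 0.1,
                       replicates = 20, base_seed = 1) {
  structure(list(spacing = spacing, max_lag = max_lag, threshold = threshold,
                 alpha = alpha, variant = variant, pooling = pooling,
                 p_remove = p_remove, replicates = replicates,
                 base_seed = base_seed),
            class = "run_config")
}

#' Decompose, fit and sample a cohort
#'
#' @param trees list of [neuron_tree()].
#' @param config a [run_config()].
#' @param degree optional degree override (e.g. 1 for the piecewise-linear
#'   control).
#' @return List of `geometry_series` across all segments of all neurons.
#' @export
cohort_geometry <- function(trees, config = run_config(), degree = NULL) {
  unlist(lapply(trees, function(tr) {
    segment_geometry(decompose_arbor(tr), spacing = config$spacing,
                     variant = config$variant, degree = degree)
  }), recursive = FALSE)
}

#' Full cohort analysis
#'
#' Runs the complete pipeline on a cohort: arbor decomposition, spline
#' fitting, geometry sampling, autocorrelation analyses of curvature and
#' torsion magnitude, the six paired class comparisons and the ordering
#' table. Requires at least 2 neurons for the statistical tests; a smaller
#' cohort returns geometry only, with a message.
#'
#' @param trees list of [neuron_tree()].
#' @param config a [run_config()].
#' @return List with elements `segments` (table), `geometry` (list of
#'   `geometry_series`), `class_values`, `autocorr_curvature`,
#'   `autocorr_torsion`, `comparisons`, `ordering` (NULL where the cohort
#'   is too small) and `config`.
#' @export
analyze_cohort <- function(trees, config = run_config()) {
  segs <- unlist(lapply(trees, decompose_arbor), recursive = FALSE)
  geoms <- lapply(segs, function(s) {
    sample_geometry(fit_segment(s), spacing = config$spacing,
                    variant = config$variant)
  })
  out <- list(
    segments = segment_table(segs),
    geometry = geoms,
    class_values = compute_class_values(geoms, pooling = config$pooling),
    autocorr_curvature = autocorr_analysis(geoms, "curvature",
                                           max_lag = config$max_lag,
                                           threshold = config$threshold,
                                           alpha = config$alpha),
    autocorr_torsion = autocorr_analysis(geoms, "torsion",
                                         max_lag = config$max_lag,
                                         threshold = config$threshold,
                                         alpha = config$alpha),
    comparisons = NULL, ordering = NULL, config = config
  )
  if (length(trees) >= 2) {
    out$comparisons <- run_class_comparisons(out$class_values,
                                             alpha = config$alpha)
    out$ordering <- ordering_counts(out$class_values)
  } else {
    message("cohort has fewer than 2 neurons: skipping statistical tests")
  }
  out
}

read_swc_inputs <- function(paths) {
  trees <- list()
  failures <- character(0)
  for (p in paths) {
    tr <- tryCatch(read_swc(p), error = function(e) {
      message("skipping ", p, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(tr)) failures <- c(failures, p) else trees[[length(trees) + 1]] <- tr
  }
  if (length(trees) == 0) stop("no readable SWC inputs (", length(failures), " failed)")
  trees
}

#' Command: tabulate arbor segments
#'
#' @param inputs character vector of SWC paths.
#' @param output optional CSV path.
#' @return The segment table, invisibly if `output` is given.
#' @export
cmd_decompose <- function(inputs, output = NULL) {
  trees <- read_swc_inputs(inputs)
  tab <- segment_table(unlist(lapply(trees, decompose_arbor), recursive = FALSE))
  if (!is.null(output)) {
    utils::write.csv(tab, output, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Command: per-sample geometry table
#'
#' @param inputs character vector of SWC paths.
#' @param config a [run_config()].
#' @param output optional CSV path.
#' @return The geometry table (`neuron_id`, `seg_class`, `t_um`,
#'   `curvature`, `torsion_magnitude`).
#' @export
cmd_geometry <- function(inputs, config = run_config(), output = NULL) {
  trees <- read_swc_inputs(inputs)
  tab <- geometry_table(cohort_geometry(trees, config))
  if (!is.null(output)) {
    utils::write.csv(tab, output, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Command: full cohort comparison analysis
#'
#' Writes class values, autocorrelation tables and comparison results as
#' CSV plus a JSON summary (including the configuration and, optionally,
#' the perturbation replicates) into `output_dir`.
#'
#' @param inputs character vector of SWC paths.
#' @param config a [run_config()].
#' @param output_dir output directory (created if needed).
#' @param perturb if TRUE, also run [perturbation_experiment()].
#' @return The [analyze_cohort()] result, invisibly.
#' @export
cmd_compare <- function(inputs, config = run_config(), output_dir = NULL,
                        perturb = FALSE) {
  trees <- read_swc_inputs(inputs)
  if (length(trees) < 2) stop("need a cohort of at least 2 neurons")
  res <- analyze_cohort(trees, config)
  pert <- NULL
  if (perturb) {
    pert <- perturbation_experiment(trees, p_remove = config$p_remove,
                                    replicates = config$replicates,
                                    base_seed = config$base_seed,
                                    config = config)
  }
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res$class_values,
                     file.path(output_dir, "class_values.csv"), row.names = FALSE)
    utils::write.csv(res$autocorr_curvature,
                     file.path(output_dir, "autocorr_curvature.csv"), row.names = FALSE)
    utils::write.csv(res$autocorr_torsion,
                     file.path(output_dir, "autocorr_torsion.csv"), row.names = FALSE)
    utils::write.csv(res$comparisons,
                     file.path(output_dir, "comparisons.csv"), row.names = FALSE)
    summary <- list(
      config = unclass(res$config),
      comparisons = res$comparisons,
      ordering = list(counts = unclass(res$ordering),
                      row_orderings = rownames(res$ordering),
                      col_orderings = colnames(res$ordering),
                      n_excluded = attr(res$ordering, "n_excluded")),
      perturbation = if (!is.null(pert)) lapply(pert, as.data.frame)
    )
    jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res$perturbation <- pert
  invisible(res)
}

#' Command: generate and write a synthetic cohort
#'
#' @param n_neurons cohort size.
#' @param output_dir directory for the SWC files and manifest.
#' @param rng_seed integer seed.
#' @return Paths of the written SWC files, invisibly.
#' @export
cmd_synth <- function(n_neurons, output_dir, rng_seed = 1) {
  trees <- make_cohort(n_neurons, rng_seed = rng_seed)
  write_cohort(trees, output_dir, seed = rng_seed)
  invisible(file.path(output_dir, paste0(vapply(trees, `[[`, "", "source_name"),
                                         ".swc")))
}
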