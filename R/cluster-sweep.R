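# End-to-end sweep: for each value of the swept parameter, a full reference
# clustering plus subsampled repetitions, the co-clustering frequency
# structure, silhouettes, per-cluster scores, and a bootstrap CI on their
# median; then the threshold and the near-optimal selection.

#' Sweep a clustering parameter and score cluster robustness
#'
#' For each value in `grid`, clusters the full data once to establish
#' reference labels, re-clusters `reps` random subsamples of
#' `fraction * n_cells` cells, converts pairwise co-clustering frequencies
#' into consensus-distance silhouettes, aggregates them per reference
#' cluster, and places a BCa bootstrap confidence interval on the median
#' per-cluster score.  The near-optimal parameter value is the one with the
#' most clusters whose median score stays at or above the highest CI lower
#' bound across the grid.
#'
#' @param x Cells x genes count matrix (dense or sparse, row names are cell
#'   ids), or a [reduced_space()] embedding.
#' @param grid Numeric vector of parameter values to sweep (unique).
#' @param parameter Which backend parameter the grid refers to:
#'   `"resolution"` (default), `"n_hvg"`, `"n_dims"`, `"knn_k"`, or
#'   `"callable"` with a user `backend` function.
#' @param reps Subsampled repetitions per grid value (default 100).
#' @param fraction Fraction of cells per repetition (default 0.8).
#' @param config [backend_config()] for the non-swept backend parameters.
#' @param resolution Resolution used when `parameter != "resolution"`.
#' @param backend Optional user clustering function (see [run_backend()]).
#' @param n_boot,conf Bootstrap resamples and confidence level for the CI
#'   on the median per-cluster score (defaults 25,000 and 0.95).
#' @param reduce_per_subsample If `TRUE` (counts input only), the
#'   normalisation/HVG/PCA embedding is recomputed on every subsample; the
#'   default reuses the full-data embedding and re-clusters only the subset
#'   graph, which removes embedding stochasticity from the robustness
#'   signal.
#' @param block_size Cells per block in the pairwise accumulations.
#' @param keep_store Keep each grid value's `frequency_store` in the result
#'   (memory scales with cells squared; off by default).
#' @param seed Master seed; every subsample and clustering seed is derived
#'   from it deterministically.
#' @return An object of class `cluster_sweep` with elements
#'   `records` (tibble: one row per grid value with `parameter`,
#'   `n_clusters`, `median`, `ci_lower`, `ci_upper`, `ci_method`),
#'   `scores` (tibble: per-cluster robustness scores for every grid value),
#'   `silhouettes` (tibble: per-cell silhouettes and reference labels),
#'   `selection` (a `sweep_selection`), `cluster_means` (list of K x K
#'   cluster-averaged co-clustering matrices), `labels` (list of reference
#'   label vectors), and the configuration used.  [tidy()] returns the
#'   per-cluster scores, [glance()] a one-row summary, [autoplot()] the
#'   silhouette distribution plot.
#' @export
#' @examples
#' sim <- simulate_reduced(k = 3, n_cells = 120, d = 4, separation = 8,
#'                         seed = 1)
#' sw <- cluster_sweep(sim$reduced, grid = c(0.3, 1), reps = 10,
#'                     config = backend_config(knn_k = 10),
#'                     n_boot = 500, seed = 1)
#' sw$selection
cluster_sweep <- function(x, grid, parameter = "resolution", reps = 100,
                          fraction = 0.8, config = backend_config(),
                          resolution = 1, backend = NULL,
                          n_boot = 25000L, conf = 0.95,
                          reduce_per_subsample = FALSE,
                          block_size = 1024L, keep_store = FALSE,
                          seed = 1L) {
  grid <- as.numeric(grid)
  if (length(grid) == 0L || anyDuplicated(grid)) {
    abort("`grid` must be a non-empty vector of unique parameter values.",
          class = "robustclust_validation_error")
  }
  if (reps < 10) {
    warn(sprintf(
      "only %d repetitions: co-clustering frequencies will be coarse; 100 is typical.",
      reps))
  }
  is_reduced <- is(x, "reduced_space")
  if (!is_reduced) validate_counts(x, "x")
  n_cells <- if (is_reduced) nrow(x$coords) else nrow(x)
  cell_ids <- cell_ids_of(x) %||% paste0("cell", seq_len(n_cells))
  if (reduce_per_subsample && is_reduced) {
    abort("`reduce_per_subsample` requires raw counts input.",
          class = "robustclust_configuration_error")
  }

  # embedding reused across the whole sweep unless the swept parameter (or
  # reduce_per_subsample) invalidates it
  shared_reduced <- NULL
  if (parameter %in% c("resolution", "knn_k") && !identical(parameter, "callable")) {
    shared_reduced <- if (is_reduced) x else
      preprocess_reduce(x, config, seed = mix_seed(seed, 0L, 0L, 7L))
  }

  records <- list(); scores_all <- list(); sil_all <- list()
  cmeans <- list(); ref_labels <- list(); stores <- list()
  missing_total <- 0

  for (g in seq_along(grid)) {
    value <- grid[g]
    eff_res <- if (parameter == "resolution") value else resolution
    eff_knn <- if (parameter == "knn_k") as.integer(value) else config$knn_k

    # embedding for this grid value (cached across its repetitions)
    grid_reduced <- shared_reduced
    if (parameter %in% c("n_hvg", "n_dims")) {
      if (is_reduced) {
        abort(sprintf(
          "sweeping `%s` requires raw counts, not a precomputed embedding.",
          parameter), class = "robustclust_configuration_error")
      }
      cfg_g <- unclass(config)
      cfg_g[[parameter]] <- as.integer(value)
      grid_reduced <- preprocess_reduce(x, do.call(backend_config, cfg_g),
                                        seed = mix_seed(seed, g, 0L, 7L))
    }

    cluster_once <- function(subset, run_seed) {
      if (identical(parameter, "callable")) {
        run_backend(x, subset = subset, parameter_name = "callable",
                    parameter_value = value, base_config = config,
                    seed = run_seed, backend = backend)
      } else {
        red <- grid_reduced %||%
          (if (is_reduced) x else preprocess_reduce(x, config, seed = run_seed))
        graph_cluster(red, subset = subset, resolution = eff_res,
                      knn_k = eff_knn, seed = run_seed)
      }
    }

    ref <- cluster_once(NULL, mix_seed(seed, g, 0L, 3L))
    runs <- draw_subsamples(n_cells, reps = reps, fraction = fraction,
                            master_seed = seed, grid_index = g)
    labels <- vector("list", reps)
    for (r in seq_len(reps)) {
      run_seed <- mix_seed(seed, g, r, 5L)
      if (reduce_per_subsample) {
        sub_red <- preprocess_reduce(x[runs[[r]], , drop = FALSE],
                                     if (parameter %in% c("n_hvg", "n_dims")) {
                                       cfg_g2 <- unclass(config)
                                       cfg_g2[[parameter]] <- as.integer(value)
                                       do.call(backend_config, cfg_g2)
                                     } else config,
                                     seed = run_seed)
        labels[[r]] <- graph_cluster(sub_red, resolution = eff_res,
                                     knn_k = eff_knn, seed = run_seed)
      } else {
        labels[[r]] <- cluster_once(runs[[r]], run_seed)
      }
    }
    store <- accumulate_cocluster(runs, labels, n_cells,
                                  cell_ids = cell_ids)
    missing_total <- missing_total + count_missing_pairs(store, block_size)

    sil <- silhouette_from_frequency(store, ref, block_size = block_size)
    sc <- per_cluster_scores(sil, ref)
    ci <- bootstrap_median_ci(sc$score, n_boot = n_boot, conf = conf,
                              seed = mix_seed(seed, g, 0L, 9L))

    records[[g]] <- tibble(
      parameter = value, n_clusters = max(ref),
      median = unname(ci["median"]), ci_lower = unname(ci["lower"]),
      ci_upper = unname(ci["upper"]), ci_method = attr(ci, "method"))
    scores_all[[g]] <- dplyr::mutate(sc, parameter = value,
                                     .before = 1L)
    sil_all[[g]] <- tibble(parameter = value, cell_id = cell_ids,
                           cluster = as.integer(ref),
                           silhouette = unname(sil))
    cmeans[[as.character(value)]] <-
      cluster_pair_means(store, ref, block_size = block_size)
    ref_labels[[as.character(value)]] <- ref
    if (keep_store) stores[[as.character(value)]] <- store
  }

  if (missing_total > 0) {
    warn(sprintf(
      paste("low co-sampling coverage: %d cell pairs were never sampled",
            "together and were assigned the maximal consensus distance;",
            "consider a larger subsample fraction or more repetitions."),
      missing_total))
  }

  records <- dplyr::bind_rows(records)
  out <- structure(list(
    records = records,
    scores = dplyr::bind_rows(scores_all),
    silhouettes = dplyr::bind_rows(sil_all),
    selection = select_parameter(records),
    cluster_means = cmeans,
    labels = ref_labels,
    stores = if (keep_store) stores else NULL,
    parameter = parameter,
    config = config,
    reps = reps, fraction = fraction, n_boot = n_boot, conf = conf,
    reduce_per_subsample = reduce_per_subsample,
    seed = seed, n_cells = n_cells,
    missing_pairs = missing_total,
    version = as.character(packageVersion("robustclust"))),
    class = "cluster_sweep")
  out
}

#' @export
print.cluster_sweep <- function(x, ...) {
  cat(sprintf(
    "<cluster_sweep> %s over {%s}; %d cells, %d reps at %.0f%%\n",
    x$parameter, paste(x$records$parameter, collapse = ", "),
    x$n_cells, x$reps, 100 * x$fraction))
  print(x$records)
  print(x$selection)
  invisible(x)
}

#' Tidy a cluster sweep into per-cluster robustness scores
#'
#' @param x A `cluster_sweep`.
#' @param ... Unused.
#' @return Tibble with `parameter`, `cluster`, `size`, `score`.
#' @method tidy cluster_sweep
#' @export
tidy.cluster_sweep <- function(x, ...) x$scores

#' One-row summary of a cluster sweep
#'
#' @param x A `cluster_sweep`.
#' @param ... Unused.
#' @return Tibble with the selected parameter value, its cluster count and
#'   median per-cluster score, the decision threshold, and the sweep size.
#' @method glance cluster_sweep
#' @export
glance.cluster_sweep <- function(x, ...) {
  sel <- x$selection
  rec <- x$records[x$records$parameter == sel$parameter, ]
  tibble(parameter = sel$parameter, n_clusters = sel$n_clusters,
         median_score = rec$median, threshold = sel$threshold,
         n_grid = nrow(x$records), reps = x$reps, fraction = x$fraction)
}
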