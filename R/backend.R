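# Built-in clustering backend: library-size normalisation -> log1p -> highly
# variable genes -> PCA -> kNN graph -> Leiden community detection at a
# resolution.  The robustness framework itself is backend-agnostic; this
# backend exists so the package runs end to end with no external workflow.

#' Backend configuration
#'
#' Parameters of the built-in clustering backend.  Defaults mirror common
#' single-cell practice: per-cell normalisation to 10,000 counts, the 3,000
#' most highly variable genes, 100 principal components, and a 20-nearest-
#' neighbour graph.
#'
#' @param n_hvg Number of highly variable genes retained before PCA.
#' @param n_dims Number of principal components (the embedding dimension).
#' @param knn_k Number of nearest neighbours for the cluster graph.
#' @param normalize_total Per-cell target sum for library-size normalisation.
#' @return A list of class `backend_config`.
#' @export
#' @examples
#' backend_config(n_hvg = 500, n_dims = 10)
backend_config <- function(n_hvg = 3000, n_dims = 100, knn_k = 20,
                           normalize_total = 1e4) {
  assert_scalar_number(n_hvg, "n_hvg", lower = 1, integerish = TRUE)
  assert_scalar_number(n_dims, "n_dims", lower = 1, integerish = TRUE)
  assert_scalar_number(knn_k, "knn_k", lower = 1, integerish = TRUE)
  assert_scalar_number(normalize_total, "normalize_total", lower = 1e-12)
  structure(list(n_hvg = as.integer(n_hvg), n_dims = as.integer(n_dims),
                 knn_k = as.integer(knn_k),
                 normalize_total = normalize_total),
            class = "backend_config")
}

#' Construct a reduced-dimension embedding container
#'
#' Wraps a cells x dimensions coordinate matrix together with a provenance
#' string.  Use this to feed a precomputed embedding (e.g. an external latent
#' space) directly into [cluster_sweep()].
#'
#' @param coords Numeric matrix, cells in rows; row names are cell ids.
#' @param provenance Free-text description of how the embedding was obtained.
#' @return An object of class `reduced_space`.
#' @export
reduced_space <- function(coords, provenance = "user-supplied") {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || any(!is.finite(coords))) {
    abort("`coords` must be a finite numeric matrix.",
          class = "robustclust_validation_error")
  }
  if (ncol(coords) < 1L || nrow(coords) < 1L) {
    abort("`coords` must have at least one cell and one dimension.",
          class = "robustclust_validation_error")
  }
  structure(list(coords = coords, d = ncol(coords), provenance = provenance),
            class = "reduced_space")
}

#' @export
print.reduced_space <- function(x, ...) {
  cat(sprintf("<reduced_space> %d cells x %d dims (%s)\n",
              nrow(x$coords), x$d, x$provenance))
  invisible(x)
}

#' Normalise, select variable genes, and embed with PCA
#'
#' The preprocessing arm of the built-in backend: each cell is scaled to
#' `config$normalize_total` total counts and log1p-transformed; the
#' `config$n_hvg` genes with the highest dispersion (variance/mean of the
#' log values) are retained, standardised to zero mean and unit variance,
#' and projected onto the top `config$n_dims` principal components.  The
#' component sign is fixed so the largest-magnitude loading is positive,
#' making the embedding fully deterministic.
#'
#' @param counts Cells x genes matrix of non-negative expression values
#'   (dense or `Matrix` sparse); row names are cell ids.
#' @param config A [backend_config()].
#' @param seed Unused by the deterministic built-in reduction; accepted so
#'   stochastic replacements honour the same signature.
#' @return A [reduced_space()] whose coordinates are the PC scores.
#' @export
#' @examples
#' counts <- matrix(rpois(600, 5), nrow = 30,
#'                  dimnames = list(paste0("c", 1:30), paste0("g", 1:20)))
#' red <- preprocess_reduce(counts, backend_config(n_hvg = 20, n_dims = 5))
#' dim(red$coords)
preprocess_reduce <- function(counts, config = backend_config(), seed = 0L) {
  validate_counts(counts)
  if (nrow(counts) < 2L) {
    abort("at least 2 cells are required.",
          class = "robustclust_validation_error")
  }
  x <- as.matrix(counts)
  lib <- rowSums(x)
  lib[lib == 0] <- 1          # empty cells map to the origin
  x <- log1p(x / lib * config$normalize_total)

  mu <- colMeans(x)
  v <- apply(x, 2L, var)
  dispersion <- ifelse(mu > 0, v / mu, 0)
  keep <- v > 0
  if (sum(keep) < config$n_dims) {
    abort(sprintf(
      "only %d features with nonzero variance; cannot compute %d components.",
      sum(keep), config$n_dims), class = "robustclust_dimensionality_error")
  }
  n_hvg <- min(config$n_hvg, sum(keep))
  hvg <- order(-dispersion, !keep, seq_along(dispersion))[seq_len(n_hvg)]
  hvg <- hvg[v[hvg] > 0]
  x <- scale(x[, hvg, drop = FALSE])

  n_dims <- min(config$n_dims, length(hvg), nrow(x))
  pc <- prcomp(x, center = FALSE, scale. = FALSE, rank. = n_dims)
  # sign convention: largest-|loading| entry of each component positive
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    w <- pc$rotation[, j]
    sign(w[which.max(abs(w))])
  }, numeric(1))
  flip[flip == 0] <- 1
  coords <- sweep(pc$x, 2L, flip, `*`)
  rownames(coords) <- rownames(counts)
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  reduced_space(coords, provenance = sprintf(
    "normalize_total=%g + log1p + top-%d HVG + %d PCs",
    config$normalize_total, n_hvg, n_dims))
}

# Union-symmetrised unweighted kNN graph over the given coordinates.
knn_graph <- function(coords, k) {
  n <- nrow(coords)
  if (k >= n) {
    abort(sprintf("knn_k (%d) must be smaller than the number of cells (%d).",
                  k, n), class = "robustclust_parameter_error")
  }
  d2 <- as.matrix(stats::dist(coords))^2
  diag(d2) <- Inf
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    adj[i, order(d2[i, ])[seq_len(k)]] <- TRUE
  }
  adj <- adj | t(adj)
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

#' Cluster cells on a kNN graph by modularity community detection
#'
#' Builds a k-nearest-neighbour graph (Euclidean distance in the reduced
#' coordinates, directed edges symmetrised by union, unweighted) over the
#' requested cell subset only, then partitions it with the Leiden algorithm
#' under the modularity objective at the given resolution.  Larger
#' resolutions yield more, smaller communities.
#'
#' @param reduced A [reduced_space()] (or bare coordinate matrix).
#' @param subset Integer indices of the cells to cluster (defaults to all).
#' @param resolution Positive resolution parameter of the modularity
#'   objective.
#' @param knn_k Neighbours per cell; must be smaller than `length(subset)`.
#' @param seed Integer seed; the partition is reproducible given the seed.
#' @param n_iterations Leiden refinement iterations.
#' @return Integer vector of cluster labels (1..K, decreasing size order),
#'   one per subset cell, named by cell id when ids are available.
#' @export
#' @examples
#' set.seed(1)
#' xy <- rbind(matrix(rnorm(60), 30), matrix(rnorm(60, 6), 30))
#' table(graph_cluster(xy, resolution = 1, knn_k = 5, seed = 1))
graph_cluster <- function(reduced, subset = NULL, resolution = 1,
                          knn_k = 20, seed = 1L, n_iterations = 10L) {
  coords <- if (is(reduced, "reduced_space")) reduced$coords else
    as.matrix(reduced)
  subset <- subset %||% seq_len(nrow(coords))
  if (length(subset) == 0L) {
    abort("`subset` must be non-empty.",
          class = "robustclust_validation_error")
  }
  assert_scalar_number(resolution, "resolution")
  if (resolution <= 0) {
    abort("`resolution` must be positive.",
          class = "robustclust_validation_error")
  }
  sub_coords <- coords[subset, , drop = FALSE]
  g <- knn_graph(sub_coords, knn_k)
  memb <- with_seed(seed, igraph::membership(igraph::cluster_leiden(
    g, objective_function = "modularity", resolution = resolution,
    n_iterations = n_iterations)))
  labels <- canonicalize_labels(as.integer(memb))
  names(labels) <- rownames(sub_coords)
  labels
}

#' Run the clustering backend with one swept parameter
#'
#' Dispatch layer that lets any backend parameter — `resolution`, `n_hvg`,
#' `n_dims`, `knn_k` — or a user-supplied clustering function be the swept
#' parameter, while everything else is held at `base_config`.
#'
#' @param x Cells x genes count matrix, or a [reduced_space()] (only valid
#'   when the swept parameter does not require re-preprocessing).
#' @param subset Integer cell indices to cluster (defaults to all cells).
#' @param parameter_name One of `"resolution"`, `"n_hvg"`, `"n_dims"`,
#'   `"knn_k"`, or `"callable"`.
#' @param parameter_value Value of the swept parameter (for `"callable"`,
#'   the value handed to the user function).
#' @param base_config A [backend_config()] supplying the non-swept
#'   parameters, plus `resolution` via the `resolution` argument.
#' @param seed Integer seed.
#' @param resolution Resolution used when it is not itself the swept
#'   parameter.
#' @param backend User clustering function for `parameter_name =
#'   "callable"`: called as `backend(x, subset, parameter_value, seed)` and
#'   required to return one integer label per subset cell.
#' @param reduced Optional precomputed [reduced_space()] reused when the
#'   swept parameter does not alter the embedding.
#' @return Integer label vector over `subset` (canonical 1..K labels).
#' @export
run_backend <- function(x, subset = NULL, parameter_name = "resolution",
                        parameter_value = 1, base_config = backend_config(),
                        seed = 1L, resolution = 1, backend = NULL,
                        reduced = NULL) {
  n_cells <- if (is(x, "reduced_space")) nrow(x$coords) else nrow(x)
  subset <- subset %||% seq_len(n_cells)

  if (identical(parameter_name, "callable")) {
    if (!is.function(backend)) {
      abort("parameter_name = \"callable\" requires a `backend` function.",
            class = "robustclust_configuration_error")
    }
    labels <- backend(x, subset, parameter_value, seed)
    if (length(labels) != length(subset)) {
      abort(sprintf(
        "user backend returned %d labels for %d cells.",
        length(labels), length(subset)),
        class = "robustclust_contract_error")
    }
    out <- canonicalize_labels(as.integer(labels))
    names(out) <- cell_ids_of(x)[subset]
    return(out)
  }

  known <- c("resolution", "n_hvg", "n_dims", "knn_k")
  if (!parameter_name %in% known) {
    abort(sprintf("unknown parameter `%s`; expected one of %s or \"callable\".",
                  parameter_name, paste0('"', known, '"', collapse = ", ")),
          class = "robustclust_configuration_error")
  }

  cfg <- unclass(base_config)
  res <- resolution
  if (parameter_name == "resolution") {
    res <- parameter_value
  } else if (parameter_name == "knn_k") {
    cfg$knn_k <- as.integer(parameter_value)
  } else {
    if (is(x, "reduced_space")) {
      abort(sprintf(
        "sweeping `%s` requires raw counts, not a precomputed embedding.",
        parameter_name), class = "robustclust_configuration_error")
    }
    cfg[[parameter_name]] <- as.integer(parameter_value)
    reduced <- NULL     # embedding depends on the swept value
  }
  cfg <- do.call(backend_config, cfg)

  if (is.null(reduced)) {
    reduced <- if (is(x, "reduced_space")) x else
      preprocess_reduce(x, cfg, seed = seed)
  }
  graph_cluster(reduced, subset = subset, resolution = res,
                knn_k = cfg$knn_k, seed = seed)
}
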