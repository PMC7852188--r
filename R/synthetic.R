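# Ground-truth-labelled synthetic data so every stage of the framework is
# testable without external downloads: a negative-binomial count simulator
# with marker-gene structure, and a fast Gaussian-blob embedding generator
# that bypasses preprocessing.

#' Simulation configuration for synthetic counts
#'
#' @param k Number of ground-truth clusters.
#' @param n_cells,n_genes Matrix dimensions.
#' @param markers_per_cluster Marker genes upregulated in each cluster
#'   (disjoint sets).
#' @param lfc Log2 fold change of marker genes over baseline.
#' @param dispersion Negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2).
#' @param overlap_pairs Optional list of length-2 integer vectors naming
#'   cluster pairs whose marker effects are scaled toward zero, emulating
#'   transcriptionally similar (hard-to-separate) cell types.
#' @param overlap_scale Multiplier applied to the log2 fold change of
#'   markers in overlapping pairs (0 erases the distinction).
#' @param proportions Cluster mixing weights (must sum to 1).
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(k = 3, n_cells = 600, n_genes = 1000,
                       markers_per_cluster = 50, lfc = 3, dispersion = 0.1,
                       overlap_pairs = list(), overlap_scale = 0.25,
                       proportions = rep(1 / k, k), seed = 1L) {
  assert_scalar_number(k, "k", lower = 1, integerish = TRUE)
  assert_scalar_number(lfc, "lfc", lower = 0)
  assert_scalar_number(dispersion, "dispersion")
  if (dispersion <= 0) {
    abort("`dispersion` must be positive.",
          class = "robustclust_validation_error")
  }
  if (length(proportions) != k || abs(sum(proportions) - 1) > 1e-8) {
    abort("`proportions` must have length k and sum to 1.",
          class = "robustclust_validation_error")
  }
  if (markers_per_cluster * k > n_genes) {
    abort(sprintf(
      "markers_per_cluster * k = %d exceeds n_genes = %d.",
      markers_per_cluster * k, n_genes),
      class = "robustclust_configuration_error")
  }
  structure(list(k = as.integer(k), n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes),
                 markers_per_cluster = as.integer(markers_per_cluster),
                 lfc = lfc, dispersion = dispersion,
                 overlap_pairs = overlap_pairs,
                 overlap_scale = overlap_scale,
                 proportions = proportions, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a ground-truth-labelled count matrix
#'
#' Per-gene baseline means are drawn log-normally; each cluster upregulates
#' its disjoint marker set by `2^lfc` (scaled by `overlap_scale` for
#' clusters listed in `overlap_pairs`); counts are negative-binomial with
#' the configured overdispersion and log-normal per-cell size factors.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (cells x genes dense matrix with cell/gene
#'   ids) and `labels` (named integer ground-truth vector).
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(k = 2, n_cells = 60, n_genes = 100))
#' table(sim$labels)
simulate_counts <- function(config = sim_config()) {
  stopifnot(is(config, "sim_config"))
  with_seed(config$seed, {
    k <- config$k; n <- config$n_cells; p <- config$n_genes
    labels <- sample.int(k, n, replace = TRUE, prob = config$proportions)
    base_mu <- rlnorm(p, meanlog = log(0.5), sdlog = 1)
    # disjoint marker blocks, cluster c owns genes ((c-1)*mpc, c*mpc]
    mpc <- config$markers_per_cluster
    lfc_by_cluster <- rep(config$lfc, k)
    for (pair in config$overlap_pairs) {
      lfc_by_cluster[pair] <- config$lfc * config$overlap_scale
    }
    mu <- matrix(base_mu, nrow = k, ncol = p, byrow = TRUE)
    for (cl in seq_len(k)) {
      if (mpc > 0) {
        idx <- ((cl - 1) * mpc + 1):(cl * mpc)
        mu[cl, idx] <- mu[cl, idx] * 2^lfc_by_cluster[cl]
      }
    }
    size_factor <- rlnorm(n, meanlog = 0, sdlog = 0.3)
    cell_mu <- mu[labels, , drop = FALSE] * size_factor
    counts <- matrix(
      rnbinom(n * p, mu = as.numeric(cell_mu), size = 1 / config$dispersion),
      nrow = n, ncol = p)
    dimnames(counts) <- list(sprintf("cell%04d", seq_len(n)),
                             sprintf("gene%04d", seq_len(p)))
    names(labels) <- rownames(counts)
    list(counts = counts, labels = labels)
  })
}

#' Simulate a labelled Gaussian-blob embedding
#'
#' Fast fixture that bypasses preprocessing entirely: `k` isotropic
#' Gaussian blobs with unit within-cluster spread and pairwise centroid
#' distance `separation`, in `d` dimensions.
#'
#' @param k Number of blobs.
#' @param n_cells Total cells (split as evenly as possible across blobs).
#' @param d Embedding dimension.
#' @param separation Pairwise centroid distance in the same units as the
#'   unit within-blob standard deviation; 0 collapses all blobs onto one
#'   cloud.
#' @param seed Integer seed.
#' @return List with `reduced` (a [reduced_space()]) and `labels` (named
#'   integer ground-truth vector).
#' @export
#' @examples
#' sim <- simulate_reduced(k = 4, n_cells = 200, d = 5, separation = 10,
#'                         seed = 1)
#' table(sim$labels)
simulate_reduced <- function(k, n_cells, d, separation, seed = 1L) {
  assert_scalar_number(k, "k", lower = 1, integerish = TRUE)
  assert_scalar_number(d, "d", lower = 1, integerish = TRUE)
  assert_scalar_number(separation, "separation", lower = 0)
  if (n_cells < 1) {
    abort("`n_cells` must be positive.",
          class = "robustclust_validation_error")
  }
  with_seed(seed, {
    labels <- sort(rep_len(seq_len(k), n_cells))
    if (k == 1L) {
      centroids <- matrix(0, 1, d)
    } else if (d >= k) {
      # scaled standard basis: exact pairwise spacing `separation`
      centroids <- diag(k) * separation / sqrt(2)
      centroids <- cbind(centroids, matrix(0, k, d - k))
    } else {
      raw <- matrix(rnorm(k * d), k, d)
      dists <- stats::dist(raw)
      centroids <- raw * separation / max(min(dists), 1e-12)
    }
    coords <- centroids[labels, , drop = FALSE] +
      matrix(rnorm(n_cells * d), n_cells, d)
    rownames(coords) <- sprintf("cell%04d", seq_len(n_cells))
    labels <- setNames(labels, rownames(coords))
    perm <- sample.int(n_cells)     # shuffle so blobs are not contiguous
    list(reduced = reduced_space(coords[perm, , drop = FALSE],
                                 provenance = sprintf(
                                   "synthetic %d-blob embedding, separation %g",
                                   k, separation)),
         labels = labels[perm])
  })
}
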