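# From co-clustering frequencies to per-cluster robustness scores and the
# parameter decision rule.

#' Per-cell silhouette scores on the consensus distance
#'
#' Standard silhouette with the consensus distance d(x, y) = 1 - f(x, y):
#' a_i is the mean distance from cell i to its own cluster (self excluded),
#' b_i the minimum over other clusters of the mean distance to that cluster,
#' and s_i = (b_i - a_i) / max(a_i, b_i).  Cells in singleton clusters score
#' 0 by convention.  Computed blockwise; every value equals the dense
#' definition exactly.
#'
#' @param store A `frequency_store` from [accumulate_cocluster()].
#' @param labels Integer reference cluster labels covering all cells.
#' @param block_size Rows per block.
#' @return Numeric vector of silhouettes in `[-1, 1]`, one per cell.
#' @export
silhouette_from_frequency <- function(store, labels, block_size = 1024L) {
  n <- store$n_cells
  if (length(labels) != n) {
    abort("`labels` must cover all cells.",
          class = "robustclust_contract_error")
  }
  labels <- as.integer(labels)
  K <- max(labels)
  if (K < 2L) {
    warn("fewer than 2 clusters: all silhouette scores are 0.")
    return(setNames(rep(0, n), store$cell_ids))
  }
  sizes <- tabulate(labels, K)
  ind <- Matrix::sparseMatrix(i = seq_len(n), j = labels, x = 1,
                              dims = c(n, K))
  s <- numeric(n)
  for (start in seq(1L, n, by = block_size)) {
    rows <- start:min(start + block_size - 1L, n)
    d <- consensus_dist_block(store, rows = rows)   # d(i, i) = 0
    sums <- as.matrix(d %*% ind)                    # |rows| x K
    own <- labels[rows]
    own_sum <- sums[cbind(seq_along(rows), own)]
    a <- ifelse(sizes[own] > 1, own_sum / (sizes[own] - 1), 0)
    means_other <- sums / rep(sizes, each = length(rows))
    means_other[cbind(seq_along(rows), own)] <- Inf
    b <- apply(means_other, 1L, min)
    si <- ifelse(sizes[own] > 1, (b - a) / pmax(a, b), 0)
    si[!is.finite(si)] <- 0    # a = b = 0: identical consensus profiles
    s[rows] <- si
  }
  setNames(s, store$cell_ids)
}

#' Aggregate silhouettes into per-cluster robustness scores
#'
#' The robustness score of a cluster is the unweighted arithmetic mean of
#' its members' silhouette scores.
#'
#' @param sil Numeric per-cell silhouette vector.
#' @param labels Integer cluster labels of the same length.
#' @return Tibble with one row per cluster (decreasing size order):
#'   `cluster`, `size`, `score`.
#' @export
per_cluster_scores <- function(sil, labels) {
  if (length(sil) != length(labels)) {
    abort("`sil` and `labels` must have the same length.",
          class = "robustclust_contract_error")
  }
  tibble(cluster = as.integer(labels), silhouette = as.numeric(sil)) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(size = dplyr::n(),
                     score = mean(.data$silhouette), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$cluster)
}

# Interpolated quantile of a bootstrap distribution on the normal scale:
# order statistic k = (R + 1) * alpha, interpolating between neighbouring
# order statistics linearly in qnorm(k / (R + 1)).
boot_quantile <- function(t_sorted, alpha) {
  R <- length(t_sorted)
  vapply(alpha, function(a) {
    rk <- (R + 1) * a
    k <- min(max(floor(rk), 1L), R - 1L)
    t1 <- t_sorted[k]; t2 <- t_sorted[k + 1L]
    if (t2 == t1) return(t1)
    g1 <- qnorm(k / (R + 1)); g2 <- qnorm((k + 1) / (R + 1))
    w <- (qnorm(min(max(a, 1 / (R + 1)), R / (R + 1))) - g1) / (g2 - g1)
    t1 + min(max(w, 0), 1) * (t2 - t1)
  }, numeric(1))
}

#' BCa bootstrap confidence interval on the median
#'
#' Bias-corrected and accelerated (BCa) nonparametric bootstrap interval on
#' the sample median: the bias correction z0 comes from the fraction of
#' bootstrap medians below the observed median and the acceleration from the
#' jackknife of the median.  Falls back to the percentile interval — with a
#' message — when BCa is undefined: fewer than 3 values, a zero-variance
#' bootstrap distribution, or a degenerate jackknife.
#'
#' @param scores Numeric vector (here: per-cluster robustness scores).
#' @param n_boot Number of bootstrap resamples (default 25,000).
#' @param conf Confidence level (default 0.95).
#' @param seed Integer seed; the interval is reproducible given the seed.
#' @return Named numeric vector `c(lower, median, upper)` with attribute
#'   `"method"` (`"bca"` or `"percentile"`).
#' @export
#' @examples
#' bootstrap_median_ci(c(0.2, 0.4, 0.6, 0.8, 1.0), n_boot = 2000, seed = 1)
bootstrap_median_ci <- function(scores, n_boot = 25000L, conf = 0.95,
                                seed = 1L) {
  scores <- as.numeric(scores)
  if (length(scores) == 0L || any(!is.finite(scores))) {
    abort("`scores` must be a non-empty finite numeric vector.",
          class = "robustclust_validation_error")
  }
  assert_scalar_number(conf, "conf")
  if (conf <= 0 || conf >= 1) {
    abort("`conf` must be in (0, 1).",
          class = "robustclust_validation_error")
  }
  n <- length(scores)
  m <- median(scores)
  t_boot <- with_seed(seed, {
    draws <- matrix(sample(scores, n * n_boot, replace = TRUE), nrow = n)
    apply(draws, 2L, median)
  })
  t_sorted <- sort(t_boot)
  alpha <- (1 - conf) / 2

  percentile <- function(why) {
    inform(sprintf(
      "BCa undefined (%s); falling back to the percentile interval.", why))
    ci <- boot_quantile(t_sorted, c(alpha, 1 - alpha))
    structure(c(lower = ci[1], median = m, upper = ci[2]),
              method = "percentile")
  }

  if (n < 3L) return(percentile("fewer than 3 values"))
  if (t_sorted[1] == t_sorted[n_boot]) {
    return(percentile("zero-variance bootstrap distribution"))
  }
  prop <- mean(t_boot < m)
  if (prop == 0 || prop == 1) {
    return(percentile("median outside the bootstrap distribution"))
  }
  z0 <- qnorm(prop)
  jack <- vapply(seq_len(n), function(i) median(scores[-i]), numeric(1))
  jm <- mean(jack) - jack
  denom <- sum(jm^2)^1.5
  if (denom == 0) return(percentile("degenerate jackknife"))
  a <- sum(jm^3) / (6 * denom)
  zq <- qnorm(c(alpha, 1 - alpha))
  adj <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  ci <- boot_quantile(t_sorted, adj)
  structure(c(lower = ci[1], median = m, upper = ci[2]), method = "bca")
}

#' Decision threshold of a sweep
#'
#' The threshold is the highest lower bound among the confidence intervals
#' of the median per-cluster score across all swept parameter values.
#'
#' @param records Tibble of parameter records with a `ci_lower` column (see
#'   [cluster_sweep()]).
#' @return The threshold, a single number.
#' @export
compute_threshold <- function(records) {
  if (nrow(records) == 0L) {
    abort("at least one parameter record is required.",
          class = "robustclust_validation_error")
  }
  max(records$ci_lower)
}

#' Select the near-optimal parameter value
#'
#' Candidates are the parameter values whose median per-cluster score is at
#' or above the decision threshold; among candidates the value yielding the
#' most reference clusters wins, with ties broken toward the smallest
#' parameter value.  The record attaining the threshold is itself always a
#' candidate, so the candidate set is never empty.
#'
#' @param records Tibble with columns `parameter`, `n_clusters`, `median`,
#'   `ci_lower` (one row per swept value; see [cluster_sweep()]).
#' @return List of class `sweep_selection`: `threshold`, `parameter`,
#'   `n_clusters`, `candidates`.
#' @export
#' @examples
#' recs <- tibble::tibble(parameter = c(0.5, 1, 2),
#'                        n_clusters = c(3L, 5L, 9L),
#'                        median = c(0.90, 0.88, 0.70),
#'                        ci_lower = c(0.85, 0.80, 0.60))
#' select_parameter(recs)
select_parameter <- function(records) {
  threshold <- compute_threshold(records)
  cand <- records[records$median >= threshold, , drop = FALSE]
  best <- cand[order(-cand$n_clusters, cand$parameter), ][1, ]
  structure(list(threshold = threshold,
                 parameter = best$parameter,
                 n_clusters = best$n_clusters,
                 candidates = cand$parameter),
            class = "sweep_selection")
}

#' @export
print.sweep_selection <- function(x, ...) {
  cat(sprintf(
    "<sweep_selection> parameter = %g (%d clusters); threshold = %.4f\n",
    x$parameter, x$n_clusters, x$threshold))
  cat("candidates:", paste(x$candidates, collapse = ", "), "\n")
  invisible(x)
}
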