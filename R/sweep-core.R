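# Subsampled repetitions and the pairwise co-clustering frequency structure.
#
# The frequency store keeps, per run, a sparse cell-inclusion indicator and a
# sparse cell-by-(run, cluster) membership indicator.  Pairwise co-occurrence
# counts m(x, y) and co-clustering counts c(x, y) are then exact sparse
# cross-products, materialised blockwise so peak memory stays bounded by the
# block size while every entry equals the dense all-pairs computation.

#' Draw the subsample index sets for a sweep
#'
#' Draws `reps` random subsets of `floor(fraction * n_cells)` cells, each
#' sampled uniformly without replacement.  Run r's seed is derived
#' deterministically from `(master_seed, grid_index, r)`, so the same run
#' uses the same cells regardless of how many repetitions or grid values the
#' sweep contains.
#'
#' @param n_cells Number of cells available.
#' @param reps Number of repetitions (default 100).
#' @param fraction Fraction of cells per repetition, in (0, 1] (default 0.8).
#' @param master_seed Integer master seed.
#' @param grid_index Index of the swept parameter value this set belongs to.
#' @return List of `reps` integer index vectors.
#' @export
#' @examples
#' draw_subsamples(10, reps = 3, fraction = 0.8, master_seed = 1)
draw_subsamples <- function(n_cells, reps = 100, fraction = 0.8,
                            master_seed = 1L, grid_index = 1L) {
  assert_scalar_number(reps, "reps", lower = 1, integerish = TRUE)
  assert_scalar_number(fraction, "fraction")
  if (fraction <= 0 || fraction > 1) {
    abort("`fraction` must be in (0, 1].",
          class = "robustclust_validation_error")
  }
  size <- floor(fraction * n_cells)
  if (size < 2) {
    abort(sprintf(
      "subsample size floor(%g * %d) = %d; at least 2 cells are required.",
      fraction, n_cells, size), class = "robustclust_parameter_error")
  }
  lapply(seq_len(reps), function(r) {
    with_seed(mix_seed(master_seed, grid_index, r, 101L),
              sort(sample.int(n_cells, size)))
  })
}

#' Accumulate co-clustering counts over subsampled runs
#'
#' For every cell pair (x, y), counts the number of runs in which both were
#' sampled, m(x, y), and the number of those runs in which they received the
#' same cluster label, c(x, y).  The co-clustering frequency is
#' f(x, y) = c/m and the consensus distance d(x, y) = 1 - f(x, y).
#'
#' @param runs List of integer index vectors, one per subsampled run.
#' @param labels List of integer label vectors, `labels[[r]]` covering
#'   exactly `runs[[r]]`.
#' @param n_cells Total number of cells the indices refer to.
#' @param cell_ids Optional cell identifiers of length `n_cells`.
#' @return A `frequency_store` object; see [freq_block()],
#'   [cocluster_frequency()], [consensus_dist_block()],
#'   [cluster_pair_means()].
#' @export
#' @examples
#' runs <- list(c(1, 2, 3), c(1, 2))
#' labs <- list(c(1, 1, 2), c(1, 2))
#' st <- accumulate_cocluster(runs, labs, n_cells = 3)
#' cocluster_frequency(st, 1, 2)   # co-clustered in 1 of 2 shared runs
accumulate_cocluster <- function(runs, labels, n_cells,
                                 cell_ids = NULL) {
  if (length(runs) != length(labels)) {
    abort("`runs` and `labels` must have the same length.",
          class = "robustclust_contract_error")
  }
  for (r in seq_along(runs)) {
    if (length(runs[[r]]) != length(labels[[r]])) {
      abort(sprintf(
        "run %d: %d sampled cells but %d labels.",
        r, length(runs[[r]]), length(labels[[r]])),
        class = "robustclust_contract_error")
    }
    if (length(runs[[r]]) &&
        (max(runs[[r]]) > n_cells || min(runs[[r]]) < 1 ||
         anyDuplicated(runs[[r]]))) {
      abort(sprintf("run %d: invalid or duplicated cell indices.", r),
            class = "robustclust_contract_error")
    }
  }
  R <- length(runs)
  # inclusion indicator: cells x runs
  incl <- Matrix::sparseMatrix(
    i = unlist(runs),
    j = rep.int(seq_len(R), lengths(runs)),
    x = 1, dims = c(n_cells, R))
  # membership indicator: cells x (run-specific clusters)
  offsets <- c(0L, cumsum(vapply(labels, function(l) {
    if (length(l)) max(as.integer(l)) else 0L
  }, integer(1))))
  memb <- Matrix::sparseMatrix(
    i = unlist(runs),
    j = unlist(lapply(seq_len(R), function(r) {
      as.integer(labels[[r]]) + offsets[r]
    })),
    x = 1, dims = c(n_cells, offsets[R + 1L]))
  structure(list(incl = incl, memb = memb, n_cells = n_cells,
                 n_runs = R, cell_ids = cell_ids),
            class = "frequency_store")
}

#' @export
print.frequency_store <- function(x, ...) {
  cat(sprintf("<frequency_store> %d cells, %d subsampled runs\n",
              x$n_cells, x$n_runs))
  invisible(x)
}

#' Extract a block of pairwise counts and frequencies
#'
#' Materialises the co-occurrence count m, co-clustering count c, and
#' frequency f = c/m for a rows x cols block of the (conceptually dense)
#' pairwise matrices.  `f` is `NA` where m = 0 (pair never co-sampled) and 1
#' on the diagonal (self-pairs, by convention).
#'
#' @param store A `frequency_store`.
#' @param rows,cols Integer cell indices (default: all cells).
#' @return List with dense matrices `m`, `c`, `f`.
#' @export
freq_block <- function(store, rows = NULL, cols = NULL) {
  rows <- rows %||% seq_len(store$n_cells)
  cols <- cols %||% seq_len(store$n_cells)
  m <- as.matrix(store$incl[rows, , drop = FALSE] %*%
                   Matrix::t(store$incl[cols, , drop = FALSE]))
  cc <- as.matrix(store$memb[rows, , drop = FALSE] %*%
                    Matrix::t(store$memb[cols, , drop = FALSE]))
  f <- ifelse(m > 0, cc / pmax(m, 1), NA_real_)
  self <- outer(rows, cols, `==`)
  f[self] <- 1
  list(m = m, c = cc, f = f)
}

#' Co-clustering frequency of a cell pair
#'
#' @param store A `frequency_store`.
#' @param x,y Cell indices.
#' @return f(x, y) in `[0, 1]`; 1 when `x == y`; `NA` when the pair was
#'   never co-sampled (its consensus distance is then 1).
#' @export
cocluster_frequency <- function(store, x, y) {
  freq_block(store, rows = x, cols = y)$f[1, 1]
}

#' Consensus distance block d = 1 - f
#'
#' Distance convention: d(x, x) = 0 and pairs never sampled together get the
#' maximal distance 1 (frequency undefined).
#'
#' @inheritParams freq_block
#' @return Dense rows x cols matrix of distances in `[0, 1]`.
#' @export
consensus_dist_block <- function(store, rows = NULL, cols = NULL) {
  f <- freq_block(store, rows, cols)$f
  d <- 1 - f
  d[is.na(d)] <- 1
  d
}

# Number of distinct off-diagonal pairs never co-sampled (m == 0), counted
# blockwise.  Used for the low-coverage warning at aggressive subsampling.
count_missing_pairs <- function(store, block_size = 1024L) {
  n <- store$n_cells
  miss <- 0
  for (start in seq(1L, n, by = block_size)) {
    rows <- start:min(start + block_size - 1L, n)
    m <- as.matrix(store$incl[rows, , drop = FALSE] %*%
                     Matrix::t(store$incl))
    zero <- m == 0
    zero[cbind(seq_along(rows), rows)] <- FALSE
    miss <- miss + sum(zero)
  }
  miss / 2
}

#' Cluster-averaged co-clustering frequencies
#'
#' Entry (i, j) is the mean co-clustering frequency f(x, y) over all pairs
#' with x in cluster i and y in cluster j, excluding self-pairs on the
#' diagonal.  The diagonal is the within-cluster co-clustering score.  Pairs
#' never co-sampled contribute frequency 0 (the maximal-distance
#' convention).
#'
#' @param store A `frequency_store`.
#' @param labels Integer cluster labels covering all cells.
#' @param block_size Rows per block in the accumulation.
#' @return K x K numeric matrix; a singleton cluster's diagonal is set to 1
#'   (no non-self pairs) and flagged via the `"singleton"` attribute.
#' @export
cluster_pair_means <- function(store, labels, block_size = 1024L) {
  n <- store$n_cells
  if (length(labels) != n) {
    abort("`labels` must cover all cells.",
          class = "robustclust_contract_error")
  }
  labels <- as.integer(labels)
  K <- max(labels)
  ind <- Matrix::sparseMatrix(i = seq_len(n), j = labels, x = 1,
                              dims = c(n, K))
  sums <- matrix(0, K, K)
  for (start in seq(1L, n, by = block_size)) {
    rows <- start:min(start + block_size - 1L, n)
    f <- freq_block(store, rows = rows)$f
    f[is.na(f)] <- 0
    f[cbind(seq_along(rows), rows)] <- 0   # drop self-pairs everywhere
    sums <- sums + as.matrix(Matrix::t(ind[rows, , drop = FALSE]) %*%
                               f %*% ind)
  }
  sizes <- tabulate(labels, K)
  npairs <- outer(sizes, sizes)
  diag(npairs) <- sizes * (sizes - 1)
  out <- ifelse(npairs > 0, sums / pmax(npairs, 1), 1)
  singleton <- sizes == 1
  diag(out)[singleton] <- 1
  dimnames(out) <- list(seq_len(K), seq_len(K))
  attr(out, "singleton") <- which(singleton)
  out
}
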