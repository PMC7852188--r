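# Independent reference implementations used as oracles.  These are kept
# deliberately naive (dense loops, exhaustive search) and share no code
# with the package internals they check.

# Dense all-pairs co-occurrence / co-clustering counts by direct looping
# over runs.
dense_cocluster_reference <- function(runs, labels, n_cells) {
  m <- matrix(0L, n_cells, n_cells)
  cc <- matrix(0L, n_cells, n_cells)
  for (r in seq_along(runs)) {
    idx <- runs[[r]]
    lab <- labels[[r]]
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        m[idx[a], idx[b]] <- m[idx[a], idx[b]] + 1L
        if (lab[a] == lab[b]) {
          cc[idx[a], idx[b]] <- cc[idx[a], idx[b]] + 1L
        }
      }
    }
  }
  list(m = m, c = cc)
}

# Consensus distance matrix implied by the reference counts (d = 1 - c/m,
# never-co-sampled pairs maximally distant, zero diagonal).
dense_distance_reference <- function(runs, labels, n_cells) {
  ref <- dense_cocluster_reference(runs, labels, n_cells)
  d <- matrix(1, n_cells, n_cells)
  pos <- ref$m > 0
  d[pos] <- 1 - ref$c[pos] / ref$m[pos]
  diag(d) <- 0
  d
}

# Textbook silhouette over an explicit distance matrix.
brute_silhouette <- function(d, labels) {
  n <- nrow(d)
  ks <- sort(unique(labels))
  vapply(seq_len(n), function(i) {
    own <- labels[i]
    own_members <- setdiff(which(labels == own), i)
    if (length(own_members) == 0L) return(0)
    a <- mean(d[i, own_members])
    b <- min(vapply(setdiff(ks, own), function(k) {
      mean(d[i, labels == k])
    }, numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

# All set partitions of 1..n as label vectors (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L)) {
      recurse(c(prefix, lab), max(maxlab, lab))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Exhaustive-search optimum of resolution-modularity over every partition.
brute_best_modularity <- function(g, resolution) {
  parts <- all_partitions(igraph::vcount(g))
  qs <- vapply(parts, function(p) {
    igraph::modularity(g, p, resolution = resolution)
  }, numeric(1))
  list(q = max(qs), membership = parts[[which.max(qs)]])
}

# Random subsampled-run fixture: n_cells cells, n_runs runs, each sampling
# `size` cells and labelling them by a random k-means-style assignment.
random_runs_fixture <- function(n_cells, n_runs, size, k = 3L) {
  runs <- lapply(seq_len(n_runs), function(r) sort(sample.int(n_cells, size)))
  labels <- lapply(runs, function(idx) sample.int(k, length(idx),
                                                  replace = TRUE))
  list(runs = runs, labels = labels)
}

# BCa interval for the median via the boot package (independent route).
boot_bca_reference <- function(scores, n_boot, conf = 0.95) {
  b <- boot::boot(scores, function(x, i) median(x[i]), R = n_boot)
  ci <- boot::boot.ci(b, conf = conf, type = "bca")
  ci$bca[1, 4:5]
}
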