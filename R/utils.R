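# Internal helpers: validation and deterministic seed derivation.

`%||%` <- rlang::`%||%`

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "robustclust_validation_error")
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(lower), format(upper), format(x)),
          class = "robustclust_validation_error")
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    abort(sprintf("`%s` must be a whole number.", name),
          class = "robustclust_validation_error")
  }
  invisible(x)
}

# Deterministic seed derivation on the Lehmer prime 2^31 - 1.  Mixing the
# master seed with a stream of integer keys (grid index, repetition index,
# role tag) gives per-run seeds that do not depend on how many repetitions
# or grid values surround them, so run r uses the same subsample whether the
# sweep asks for 50 or 100 repetitions.
mix_seed <- function(master, ...) {
  p <- 2147483647
  s <- as.numeric(master) %% p
  for (k in c(...)) {
    # 48271 * (p - 1) < 2^53: exact in double arithmetic
    s <- (s * 48271 + as.numeric(k) + 1) %% p
  }
  as.integer(s %% (p - 1) + 1)
}

# Evaluate `code` under a locally-set RNG state, restoring the caller's.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Canonical cluster labels: contiguous integers 1..K assigned in decreasing
# cluster-size order (ties broken by first appearance), so cluster 1 is
# always the largest.  Downstream statistics are label-permutation
# invariant; canonicalisation only stabilises reporting.
canonicalize_labels <- function(labels) {
  labels <- as.integer(labels)
  tab <- table(labels)
  first_seen <- match(names(tab), as.character(labels))
  ord <- order(-as.integer(tab), first_seen)
  map <- setNames(seq_along(ord), names(tab)[ord])
  out <- unname(map[as.character(labels)])
  names(out) <- names(labels)
  out
}

validate_counts <- function(counts, arg = "counts") {
  if (!(is.matrix(counts) || is(counts, "Matrix"))) {
    abort(sprintf("`%s` must be a cells x features matrix.", arg),
          class = "robustclust_validation_error")
  }
  # sparse: only stored entries can be non-finite or negative
  vals <- if (is(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  if (length(vals) && any(!is.finite(vals))) {
    abort(sprintf("`%s` contains non-finite values.", arg),
          class = "robustclust_validation_error")
  }
  if (length(vals) && min(vals) < 0) {
    abort(sprintf("`%s` contains negative values.", arg),
          class = "robustclust_validation_error")
  }
  for (dn in dimnames(counts)) {
    if (!is.null(dn) && anyDuplicated(dn)) {
      abort(sprintf("`%s` has duplicated identifiers.", arg),
            class = "robustclust_validation_error")
    }
  }
  invisible(counts)
}

cell_ids_of <- function(x) {
  if (is(x, "reduced_space")) rownames(x$coords) else rownames(x)
}
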