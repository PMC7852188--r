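# Agreement between two partitionings via Dice coefficients.

#' Dice coefficient matrix between two partitionings
#'
#' For every cluster pair (A_i, B_j) across two labelings of the same cells,
#' computes the set-overlap Dice coefficient
#' D = 2 |A_i intersect B_j| / (|A_i| + |B_j|).  When both label vectors are
#' named, cells are matched by id and cells present in only one labeling are
#' dropped (with a message stating how many); unnamed vectors are matched by
#' position and must have equal length.
#'
#' @param labels_a,labels_b Integer (or factor/character) cluster label
#'   vectors, optionally named by cell id.
#' @return A `dice_matrix`: the K_A x K_B coefficient matrix with attributes
#'   `sizes_a`, `sizes_b` (cluster sizes after matching).  [tidy()] returns
#'   the long form.
#' @export
#' @examples
#' a <- c(x1 = 1, x2 = 1, x3 = 1)
#' b <- c(x2 = 1, x3 = 1, x4 = 1)
#' dice_matrix(a, b)    # single overlap of 2 cells: 2*2/(3+3)
dice_matrix <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    common <- intersect(names(labels_a), names(labels_b))
    if (length(common) == 0L) {
      abort("the two labelings share no cell ids.",
            class = "robustclust_validation_error")
    }
    dropped <- (length(labels_a) - length(common)) +
      (length(labels_b) - length(common))
    if (dropped > 0) {
      inform(sprintf(
        "%d cells present in only one labeling were dropped.", dropped))
    }
    labels_a <- labels_a[common]
    labels_b <- labels_b[common]
  } else if (length(labels_a) != length(labels_b)) {
    abort("unnamed labelings must cover the same cells (equal length).",
          class = "robustclust_validation_error")
  }
  fa <- factor(labels_a)
  fb <- factor(labels_b)
  ct <- table(fa, fb)
  sizes_a <- rowSums(ct)
  sizes_b <- colSums(ct)
  d <- 2 * unclass(ct) / outer(sizes_a, sizes_b, `+`)
  structure(as.matrix(d), class = "dice_matrix",
            sizes_a = sizes_a, sizes_b = sizes_b)
}

#' @export
print.dice_matrix <- function(x, ...) {
  cat(sprintf("<dice_matrix> %d x %d clusters\n", nrow(x), ncol(x)))
  print(round(unclass(x)[, , drop = FALSE], 3))
  invisible(x)
}

#' Long-form Dice coefficients
#'
#' @param x A `dice_matrix`.
#' @param ... Unused.
#' @return Tibble with `cluster_a`, `cluster_b`, `size_a`, `size_b`, `dice`.
#' @method tidy dice_matrix
#' @export
tidy.dice_matrix <- function(x, ...) {
  m <- unclass(x)
  attr(m, "sizes_a") <- attr(m, "sizes_b") <- NULL
  tibble(
    cluster_a = rep(rownames(m), times = ncol(m)),
    cluster_b = rep(colnames(m), each = nrow(m)),
    size_a = rep(unname(attr(x, "sizes_a")), times = ncol(m)),
    size_b = rep(unname(attr(x, "sizes_b")), each = nrow(m)),
    dice = as.numeric(m))
}

#' Best-matching partner per cluster
#'
#' Row-wise (or column-wise) maxima of a Dice matrix: for each cluster of
#' one partitioning, the strongest overlap it achieves in the other, and
#' which partner cluster achieves it.
#'
#' @param dice A `dice_matrix`.
#' @param axis `"rows"` (default) or `"columns"`.
#' @return Tibble with `cluster`, `max_dice`, `partner`.
#' @export
max_dice_per_cluster <- function(dice, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  m <- unclass(dice)
  if (axis == "columns") m <- t(m)
  if (nrow(m) == 0L || ncol(m) == 0L) {
    abort("empty Dice matrix.", class = "robustclust_validation_error")
  }
  idx <- apply(m, 1L, which.max)
  tibble(cluster = rownames(m) %||% as.character(seq_len(nrow(m))),
         max_dice = m[cbind(seq_len(nrow(m)), idx)],
         partner = colnames(m)[idx] %||% as.character(idx))
}
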