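# Diagnostic figures: the silhouette distribution across the parameter
# grid, and the cluster-averaged co-clustering heatmap.

#' Silhouette distribution plot across the parameter grid
#'
#' One dot per cluster per parameter value (its robustness score), the
#' median per-cluster score with its confidence interval per parameter
#' value, a vertical line at the selected near-optimal value, and a
#' horizontal line at the decision threshold.
#'
#' @param sweep A [cluster_sweep()] result.
#' @return A ggplot object.
#' @export
plot_silhouette_distribution <- function(sweep) {
  scores <- sweep$scores
  records <- sweep$records
  empty <- setdiff(records$parameter, unique(scores$parameter))
  if (length(empty)) {
    warn(sprintf("no cluster scores at parameter value(s) %s; skipped.",
                 paste(empty, collapse = ", ")))
    records <- records[!records$parameter %in% empty, , drop = FALSE]
  }
  sel <- sweep$selection
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = factor(.data$parameter),
                               y = .data$score)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.6, size = 1.6) +
    ggplot2::geom_pointrange(
      data = records,
      ggplot2::aes(x = factor(.data$parameter), y = .data$median,
                   ymin = .data$ci_lower, ymax = .data$ci_upper),
      colour = "grey30", fatten = 2) +
    ggplot2::geom_vline(
      xintercept = match(sel$parameter, sort(unique(records$parameter))),
      colour = "red", linetype = "solid") +
    ggplot2::geom_hline(yintercept = sel$threshold, colour = "blue",
                        linetype = "dashed") +
    ggplot2::labs(x = sweep$parameter, y = "per-cluster robustness score",
                  title = "Cluster robustness across the parameter grid",
                  subtitle = sprintf(
                    "red: selected value %g; blue: decision threshold %.3f",
                    sel$parameter, sel$threshold)) +
    ggplot2::ylim(min(0, min(scores$score)), 1) +
    ggplot2::theme_minimal()
}

#' @rdname plot_silhouette_distribution
#' @param object A `cluster_sweep` (autoplot interface).
#' @param ... Unused.
#' @method autoplot cluster_sweep
#' @export
autoplot.cluster_sweep <- function(object, ...) {
  plot_silhouette_distribution(object)
}

#' Cluster-averaged co-clustering heatmap
#'
#' Heatmap of the K x K matrix of mean co-clustering frequencies at one
#' parameter value (default: the selected one); clusters are ordered by
#' their within-cluster (diagonal) score.
#'
#' @param sweep A [cluster_sweep()] result.
#' @param parameter Grid value to plot (default: selected).
#' @return A ggplot object.
#' @export
plot_cocluster_heatmap <- function(sweep, parameter = NULL) {
  parameter <- parameter %||% sweep$selection$parameter
  cm <- sweep$cluster_means[[as.character(parameter)]]
  if (is.null(cm)) {
    abort(sprintf("no cluster means stored for parameter %s.", parameter),
          class = "robustclust_validation_error")
  }
  ord <- order(-diag(cm))
  cm <- cm[ord, ord, drop = FALSE]
  df <- tibble(
    cluster_a = factor(rep(rownames(cm), times = ncol(cm)),
                       levels = rownames(cm)),
    cluster_b = factor(rep(colnames(cm), each = nrow(cm)),
                       levels = colnames(cm)),
    frequency = as.numeric(cm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster_b,
                                   y = .data$cluster_a,
                                   fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "cluster", y = "cluster",
                  fill = "mean co-clustering\nfrequency",
                  title = sprintf(
                    "Cluster-averaged co-clustering at %s = %g",
                    sweep$parameter, as.numeric(parameter))) +
    ggplot2::theme_minimal()
}
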