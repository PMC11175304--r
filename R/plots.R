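#' Score plot of a fitted cluster-to-classes model
#'
#' Projected training instances coloured by class, with the KMeans centroids
#' drawn as crosses.  With a single component, scores are plotted against
#' instance rank.
#'
#' @param object A `cv_clusterfit` (fitted with training scores retained).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_clusterfit <- function(object, ...) {
  z <- object$train_scores
  if (is.null(z)) abort("this model carries no training scores (loaded from disk?)")
  if (ncol(z) >= 2) {
    df <- tibble::tibble(c1 = z[, 1], c2 = z[, 2],
                         class = object$train_labels)
    cen <- tibble::tibble(c1 = object$centroids[, 1],
                          c2 = object$centroids[, 2])
    ggplot2::ggplot(df, ggplot2::aes(x = .data$c1, y = .data$c2)) +
      ggplot2::geom_point(ggplot2::aes(colour = .data$class), alpha = 0.7) +
      ggplot2::geom_point(data = cen, shape = 4, size = 4, stroke = 1.5) +
      ggplot2::labs(
        x = sprintf("Component 1 (%.1f%%)", 100 * object$projection$explained_fraction[1]),
        y = sprintf("Component 2 (%.1f%%)", 100 * object$projection$explained_fraction[2]),
        colour = "Class",
        title = sprintf("%s + KMeans score plot", toupper(object$projection$method))
      ) +
      ggplot2::theme_minimal()
  } else {
    df <- tibble::tibble(rank = seq_len(nrow(z)), c1 = z[, 1],
                         class = object$train_labels)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$c1,
                                     colour = .data$class)) +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::labs(x = "Instance", y = "Component 1", colour = "Class") +
      ggplot2::theme_minimal()
  }
}

#' Feature-relevance bar plot
#'
#' Transformation-matrix coefficients by feature position, coloured by source
#' sensor block and faceted by component — a direct view of which regions of
#' the concatenated voltammogram drive the projection.
#'
#' @param model A `cv_projection` or `cv_clusterfit`.
#' @param components Which components to show (default: all).
#' @return A ggplot object.
#' @export
plot_relevance <- function(model, components = NULL) {
  rel <- feature_relevance(model)
  if (!is.null(components)) rel <- rel[rel$component %in% components, ]
  ggplot2::ggplot(rel, ggplot2::aes(x = .data$feature, y = .data$coefficient,
                                    colour = .data$sensor)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$feature, yend = 0),
                          linewidth = 0.3) +
    ggplot2::facet_wrap(~ component, ncol = 1,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Feature position", y = "Coefficient",
                  colour = "Sensor block") +
    ggplot2::theme_minimal()
}

#' Per-run metric distribution of a repeated evaluation
#'
#' @param object A `cv_eval`.
#' @param metric Metric column to plot (default `"f1"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_eval <- function(object, metric = "f1", ...) {
  ggplot2::ggplot(object$runs,
                  ggplot2::aes(x = .data$method, y = .data[[metric]])) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = paste0(metric, " (%)")) +
    ggplot2::theme_minimal()
}
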