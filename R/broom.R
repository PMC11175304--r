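#' Tidy a fitted cluster-to-classes model
#'
#' Returns the transformation-matrix coefficients, one row per feature and
#' component, annotated with the source sensor block (see
#' [feature_relevance()]).
#'
#' @param x A `cv_clusterfit`.
#' @param ... Unused.
#' @return A tibble with columns `component`, `feature`, `sensor`,
#'   `coefficient`.
#' @export
tidy.cv_clusterfit <- function(x, ...) feature_relevance(x)

#' @rdname tidy.cv_clusterfit
#' @export
tidy.cv_projection <- function(x, ...) feature_relevance(x)

#' One-row summary of a fitted cluster-to-classes model
#'
#' @param x A `cv_clusterfit`.
#' @param ... Unused.
#' @return A one-row tibble: projection method, feature and component counts,
#'   number of clusters, per-component explained variance fractions.
#' @export
glance.cv_clusterfit <- function(x, ...) {
  proj <- x$projection
  tibble::tibble(
    method = proj$method,
    n_features = nrow(proj$rotation),
    n_components = proj$ncomp,
    n_clusters = nrow(x$centroids),
    n_classes = length(x$levels),
    explained = paste(sprintf("%.3f", proj$explained_fraction), collapse = "/")
  )
}

#' Per-run metrics of a repeated evaluation
#'
#' @param x A `cv_eval`.
#' @param ... Unused.
#' @return The per-run tibble (method, run, seed, split sizes, recall,
#'   precision, f1, accuracy, majority_accuracy; metrics in percent).
#' @export
tidy.cv_eval <- function(x, ...) x$runs

#' Averaged metrics of a repeated evaluation
#'
#' @param x A `cv_eval`.
#' @param ... Unused.
#' @return The per-method summary tibble of run-averaged metrics (percent).
#' @export
glance.cv_eval <- function(x, ...) x$summary
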