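#' Fit a linear projection (LDA or PCA)
#'
#' Both methods produce a transformation matrix `T` (features x components)
#' applied to centered data, so the transformed coordinates are
#' `(X - center) %*% T`.  PCA columns are the leading eigenvectors of the
#' covariance matrix ordered by eigenvalue.  LDA solves the generalized
#' eigenproblem maximizing between-class relative to within-class scatter via
#' an SVD solver suited to more features than instances: the data are
#' whitened in the span of the within-class scatter (rank-truncating singular
#' values below `tol` times the largest — the regularizer, recorded on the
#' fitted object), and the class means are then rotated to their principal
#' separating directions.  At most `n_classes - 1` LDA components exist.
#' Columns of `T` are scaled to unit norm so coefficient magnitudes are
#' comparable across components; per-component explained variance fractions
#' are computed before this normalization.
#'
#' @param x Numeric matrix (instances x features) or a `cv_instances` tibble.
#' @param y Class labels (ignored by PCA).
#' @param method `"lda"` or `"pca"`.
#' @param ncomp Number of components; defaults to `n_classes - 1` for LDA and
#'   to the same value for PCA (for comparability), capped at the permitted
#'   maximum.
#' @param tol Relative singular-value cutoff of the LDA within-class
#'   whitening.
#' @return An object of class `cv_projection` with elements `rotation` (the
#'   matrix `T`), `center`, `method`, `ncomp`, `explained_fraction` and
#'   `block_lengths` (when `x` carries them).
#' @export
fit_projection <- function(x, y = NULL, method = c("lda", "pca"), ncomp = NULL,
                           tol = 1e-8) {
  method <- match.arg(method)
  block_lengths <- if (inherits(x, "cv_instances")) attr(x, "block_lengths")
  X <- if (inherits(x, "cv_instances")) instance_matrix(x) else as.matrix(x)
  d <- nrow(X); m <- ncol(X)
  if (d < 2) abort("need at least 2 instances")

  if (method == "pca") {
    max_c <- min(m, d - 1)
    ncomp <- ncomp %||% if (!is.null(y)) min(length(unique(y)) - 1L, max_c) else max_c
    if (ncomp < 1 || ncomp > max_c) {
      abort(paste0("component-count error: ncomp must be in 1..", max_c))
    }
    pc <- prcomp(X, center = TRUE, scale. = FALSE, rank. = ncomp)
    rot <- unname(pc$rotation[, seq_len(ncomp), drop = FALSE])
    expl <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(ncomp)]
    out <- list(rotation = rot, center = pc$center, method = "pca",
                ncomp = ncomp, explained_fraction = expl,
                block_lengths = block_lengths, tol = NA_real_)
    return(structure(out, class = "cv_projection"))
  }

  if (is.null(y)) abort("LDA is supervised: labels y are required")
  y <- factor(y)
  K <- nlevels(y)
  if (K < 2) abort("LDA needs at least 2 classes")
  nk <- tabulate(y, nbins = K)
  if (any(nk < 2)) abort("LDA needs at least 2 instances per class")
  max_c <- min(K - 1L, m)
  ncomp <- ncomp %||% max_c
  if (ncomp < 1 || ncomp > max_c) {
    abort(paste0("component-count error: for ", K,
                 " classes at most ", max_c, " LDA components exist"))
  }

  xbar <- colMeans(X)
  M <- rowsum(X, y) / nk                       # K x m class means
  Xw <- X - M[as.integer(y), , drop = FALSE]   # within-class centered
  std <- sqrt(colSums(Xw^2) / (d - K))
  std[std < .Machine$double.eps] <- 1
  sv <- svd(sweep(Xw, 2, std, "/") / sqrt(d - K), nu = 0)
  rank <- sum(sv$d > tol * max(sv$d))
  if (rank == 0) {
    abort("within-class scatter has rank 0; LDA directions are undefined")
  }
  # whitening map of the within-class scatter, restricted to its span
  A <- sweep(sv$v[, seq_len(rank), drop = FALSE], 1, std, "/")
  A <- sweep(A, 2, sv$d[seq_len(rank)], "/")
  B <- sweep(M, 2, xbar) * sqrt(nk / d)        # weighted centered class means
  sb <- svd(B %*% A, nu = 0)
  rot <- A %*% sb$v[, seq_len(ncomp), drop = FALSE]
  ev <- sb$d^2
  expl <- (ev / sum(ev))[seq_len(ncomp)]
  norms <- sqrt(colSums(rot^2))
  rot <- sweep(rot, 2, norms, "/")
  structure(
    list(rotation = unname(rot), center = xbar, method = "lda", ncomp = ncomp,
         explained_fraction = expl, block_lengths = block_lengths, tol = tol),
    class = "cv_projection"
  )
}

#' Project instances into the reduced space
#'
#' Applies the fitted transformation: centers the rows and multiplies by the
#' transformation matrix, `(X - center) %*% T`.
#'
#' @param model A `cv_projection`.
#' @param x Numeric matrix or `cv_instances` with the same feature count the
#'   model was fitted on.
#' @return Numeric score matrix, instances x components.
#' @export
project <- function(model, x) {
  X <- if (inherits(x, "cv_instances")) instance_matrix(x) else as.matrix(x)
  if (ncol(X) != nrow(model$rotation)) {
    abort(paste0("dimensionality error: model expects ", nrow(model$rotation),
                 " features, got ", ncol(X)))
  }
  sweep(X, 2, model$center) %*% model$rotation
}

#' @export
print.cv_projection <- function(x, ...) {
  cat(sprintf("<cv_projection> %s, %d feature(s) -> %d component(s)\n",
              toupper(x$method), nrow(x$rotation), x$ncomp))
  cat("  explained variance fractions:",
      paste(sprintf("%.3f", x$explained_fraction), collapse = ", "), "\n")
  invisible(x)
}

#' Cluster transformed training data and label clusters by majority class
#'
#' Runs KMeans (with `nstart` restarts under the given seed) on the projected
#' training scores and assigns each cluster the class to which the majority of
#' its member points belong; ties resolve to the lowest class index and are
#' reported.  Should KMeans return an empty cluster, the fit is retried with a
#' shifted seed up to five times.
#'
#' @param z Score matrix (instances x components).
#' @param y Training labels.
#' @param n_clusters Number of clusters, at least the number of classes
#'   (default: number of classes).
#' @param seed Integer seed for the restarts (`NULL` uses the current RNG
#'   state).
#' @param nstart Random restarts per fit.
#' @param quiet Suppress tie messages.
#' @return A list with `centroids` (matrix) and `cluster_to_class` (factor,
#'   one label per cluster).
#' @export
kmeans_cluster_to_classes <- function(z, y, n_clusters = NULL, seed = NULL,
                                      nstart = 10, quiet = FALSE) {
  y <- factor(y)
  K <- nlevels(y)
  n_clusters <- n_clusters %||% K
  if (n_clusters < K) {
    abort(paste0("n_clusters (", n_clusters, ") must be at least the number of classes (", K, ")"))
  }
  z <- as.matrix(z)
  if (nrow(z) == 0) abort("empty score matrix")

  fit_once <- function(s) {
    run <- function() kmeans(z, centers = n_clusters, nstart = nstart)
    if (is.null(s)) run() else withr::with_seed(s, run())
  }
  km <- NULL
  for (try in 0:5) {
    km <- tryCatch(fit_once(if (is.null(seed)) NULL else seed + try * 1000L),
                   error = function(e) e)
    if (!inherits(km, "error") && all(km$size > 0)) break
  }
  if (inherits(km, "error")) {
    abort(paste0("KMeans failed after retries: ", conditionMessage(km)))
  }

  labels <- purrr::map_chr(seq_len(n_clusters), function(cl) {
    tab <- table(y[km$cluster == cl])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1 && !quiet) {
      inform(paste0("cluster ", cl, ": majority tie between ",
                    paste(top, collapse = ", "),
                    "; resolved to lowest class index (", top[1], ")"))
    }
    top[1]  # level order = lowest class index
  })
  list(centroids = km$centers,
       cluster_to_class = factor(labels, levels = levels(y)))
}

#' Fit a projection + KMeans cluster-to-classes classifier
#'
#' The full cluster-to-classes model: project the training instances (LDA or
#' PCA), cluster the projected scores with KMeans, label each cluster with the
#' majority class of its members, and classify new points by the class of the
#' nearest centroid (Euclidean distance).
#'
#' @inheritParams fit_projection
#' @inheritParams kmeans_cluster_to_classes
#' @param x Feature matrix or `cv_instances`.
#' @param y Training labels.
#' @return An object of class `cv_clusterfit` holding the projection, the
#'   centroids, the cluster-to-class map and the training scores.
#' @export
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 4), 20))
#' y <- rep(c("a", "b"), each = 20)
#' fit <- fit_cluster_classifier(x, y, method = "lda", seed = 1)
#' table(predict(fit, x), y)
fit_cluster_classifier <- function(x, y, method = c("lda", "pca"), ncomp = NULL,
                                   n_clusters = NULL, seed = NULL, nstart = 10,
                                   tol = 1e-8, quiet = FALSE) {
  method <- match.arg(method)
  y <- factor(y)
  proj <- fit_projection(x, y, method = method, ncomp = ncomp, tol = tol)
  z <- project(proj, x)
  cl <- kmeans_cluster_to_classes(z, y, n_clusters = n_clusters, seed = seed,
                                  nstart = nstart, quiet = quiet)
  structure(
    list(projection = proj, centroids = cl$centroids,
         cluster_to_class = cl$cluster_to_class,
         levels = levels(y), train_scores = z, train_labels = y,
         seed = seed),
    class = "cv_clusterfit"
  )
}

#' Predict classes by nearest centroid
#'
#' Test instances are projected with the training transformation and assigned
#' the class label of the nearest KMeans centroid under Euclidean distance;
#' exact distance ties resolve to the lowest cluster index.
#'
#' @param object A `cv_clusterfit`.
#' @param newdata Feature matrix or `cv_instances`.
#' @param ... Unused.
#' @return Factor of predicted class labels.
#' @export
predict.cv_clusterfit <- function(object, newdata, ...) {
  z <- project(object$projection, newdata)
  d2 <- outer(rowSums(z^2), rep(1, nrow(object$centroids))) -
    2 * z %*% t(object$centroids) +
    outer(rep(1, nrow(z)), rowSums(object$centroids^2))
  nearest <- apply(d2, 1, which.min)  # which.min takes the lowest index on ties
  object$cluster_to_class[nearest]
}

#' @export
print.cv_clusterfit <- function(x, ...) {
  cat(sprintf("<cv_clusterfit> %s + KMeans (%d clusters), classes: %s\n",
              toupper(x$projection$method), nrow(x$centroids),
              paste(x$levels, collapse = ", ")))
  invisible(x)
}

#' Transformation-matrix feature relevance
#'
#' Returns the coefficients of the (unit-norm) transformation matrix indexed
#' by feature position and annotated with the source sensor block, for
#' inspecting which parts of the concatenated voltammogram drive the
#' projection.
#'
#' @param model A `cv_projection` or `cv_clusterfit`.
#' @return A tibble with columns `component`, `feature` (1-based position),
#'   `sensor` (factor, `NA` when block lengths are unknown) and `coefficient`.
#' @export
feature_relevance <- function(model) {
  proj <- if (inherits(model, "cv_clusterfit")) model$projection else model
  if (!inherits(proj, "cv_projection")) {
    abort("feature_relevance expects a cv_projection or cv_clusterfit")
  }
  m <- nrow(proj$rotation)
  bl <- proj$block_lengths
  sensor <- if (!is.null(bl)) {
    factor(rep(names(bl), bl), levels = names(bl))
  } else {
    factor(rep(NA_character_, m))
  }
  purrr::map(seq_len(proj$ncomp), function(cc) {
    tibble::tibble(component = cc, feature = seq_len(m), sensor = sensor,
                   coefficient = proj$rotation[, cc])
  }) |> purrr::list_rbind()
}

#' Save / load a fitted cluster-to-classes model
#'
#' Serializes the transformation matrix, centering vector, centroids,
#' cluster-to-class map and block metadata to a single JSON file at full
#' precision, for prediction-only reuse.
#'
#' @param model A `cv_clusterfit`.
#' @param path File path.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns a
#'   `cv_clusterfit` (without training scores).
#' @export
write_model <- function(model, path) {
  proj <- model$projection
  obj <- list(
    format = "etongue-cluster-model-v1",
    method = proj$method,
    ncomp = proj$ncomp,
    tol = proj$tol,
    rotation = proj$rotation,
    center = proj$center,
    explained_fraction = proj$explained_fraction,
    block_lengths = as.list(proj$block_lengths),
    centroids = model$centroids,
    cluster_to_class = as.character(model$cluster_to_class),
    levels = model$levels
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "etongue-cluster-model-v1")) {
    abort(paste0("not an etongue cluster model file: ", path))
  }
  bl <- unlist(obj$block_lengths)
  proj <- structure(
    list(rotation = as.matrix(obj$rotation), center = as.numeric(obj$center),
         method = obj$method, ncomp = obj$ncomp,
         explained_fraction = as.numeric(obj$explained_fraction),
         block_lengths = if (length(bl)) bl else NULL, tol = obj$tol),
    class = "cv_projection"
  )
  structure(
    list(projection = proj, centroids = as.matrix(obj$centroids),
         cluster_to_class = factor(obj$cluster_to_class, levels = obj$levels),
         levels = obj$levels, train_scores = NULL, train_labels = NULL,
         seed = NULL),
    class = "cv_clusterfit"
  )
}
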