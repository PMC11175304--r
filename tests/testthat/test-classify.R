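test_that("the projection transform is the centered matrix product", {
  withr::with_seed(11, {
    X <- matrix(rnorm(20 * 6), 20, 6)
    y <- factor(rep(c("a", "b"), each = 10))
    for (method in c("pca", "lda")) {
      fit <- fit_projection(X, y, method = method,
                            ncomp = if (method == "lda") 1 else 3)
      brute <- sweep(X, 2, fit$center) %*% fit$rotation
      expect_lt(max(abs(project(fit, X) - brute)), 1e-10)
    }
  })
})

test_that("LDA component count is capped at classes minus one", {
  b <- make_blobs(n = 10, centers = rbind(c(0, 0, 0), c(5, 0, 0), c(0, 5, 0)))
  fit <- fit_projection(b$x, b$y, method = "lda")
  expect_identical(fit$ncomp, 2L)
  expect_error(fit_projection(b$x, b$y, method = "lda", ncomp = 3),
               "component-count")
})

test_that("full-rank PCA conserves total variance", {
  withr::with_seed(2, X <- matrix(rnorm(30 * 4), 30, 4))
  fit <- fit_projection(X, method = "pca", ncomp = 4)
  z <- project(fit, X)
  expect_equal(sum(apply(z, 2, stats::var)),
               sum(apply(scale(X, scale = FALSE), 2, stats::var)),
               tolerance = 1e-10)
  expect_equal(sum(fit$explained_fraction), 1, tolerance = 1e-10)
})

test_that("two-class LDA matches the closed-form Fisher direction", {
  # classes separated along axis 1 only; oracle: solve(Sw) %*% (mu1 - mu2)
  b <- make_blobs(n = 40, centers = rbind(c(0, 0), c(4, 0)), sd = 1, seed = 5)
  fit <- fit_projection(b$x, b$y, method = "lda", ncomp = 1)

  idx <- split(seq_along(b$y), b$y)
  mu <- lapply(idx, function(i) colMeans(b$x[i, ]))
  sw <- Reduce(`+`, lapply(idx, function(i) {
    xc <- scale(b$x[i, ], scale = FALSE)
    t(xc) %*% xc
  }))
  fisher <- solve(sw, mu[[1]] - mu[[2]])
  cosang <- abs(sum(fisher * fit$rotation[, 1])) /
    sqrt(sum(fisher^2) * sum(fit$rotation[, 1]^2))
  expect_lt(acos(pmin(cosang, 1)), 1e-6)
  # and the direction is essentially the separating axis
  expect_gt(abs(fit$rotation[1, 1]), 0.99)
})

test_that("PCA ignores labels while LDA uses them", {
  b <- make_blobs(n = 15, seed = 7)
  shuffled <- withr::with_seed(8, sample(b$y))
  pca1 <- fit_projection(b$x, b$y, method = "pca", ncomp = 2)
  pca2 <- fit_projection(b$x, shuffled, method = "pca", ncomp = 2)
  expect_identical(pca1$rotation, pca2$rotation)
  lda1 <- fit_projection(b$x, b$y, method = "lda")
  lda2 <- fit_projection(b$x, shuffled, method = "lda")
  expect_gt(max(abs(lda1$rotation - lda2$rotation)), 1e-6)
})

test_that("clusters are labeled by the majority class with lowest-index ties", {
  b <- make_blobs(n = 12, seed = 3)
  cl <- kmeans_cluster_to_classes(b$x, b$y, seed = 1, quiet = TRUE)
  # well-separated single-class blobs: the three cluster labels are the classes
  expect_setequal(as.character(cl$cluster_to_class), c("a", "b", "c"))

  # majority rule on a constructed clustering: points {a, a, b} near one center
  z <- matrix(c(0, 0, 0.1, 0, 0, 0.1, 9, 9, 9.1, 9, 9, 9.1), ncol = 2, byrow = TRUE)
  y <- factor(c("a", "a", "b", "b", "b", "a"), levels = c("a", "b"))
  cl2 <- kmeans_cluster_to_classes(z, y, n_clusters = 2, seed = 1, quiet = TRUE)
  expect_setequal(as.character(cl2$cluster_to_class), c("a", "b"))

  # exact tie resolves to the lowest class index and is reported
  zt <- matrix(c(0, 0, 0.1, 0.1, 8, 8, 8.1, 8.1), ncol = 2, byrow = TRUE)
  yt <- factor(c("a", "b", "a", "b"))
  expect_message(
    clt <- kmeans_cluster_to_classes(zt, yt, n_clusters = 2, seed = 2),
    "tie"
  )
  expect_identical(as.character(unique(clt$cluster_to_class)), "a")
})

test_that("nearest-centroid prediction inherits the cluster's class", {
  b <- make_blobs(n = 20, seed = 4)
  fit <- fit_cluster_classifier(b$x, b$y, method = "lda", seed = 1, quiet = TRUE)

  # a point exactly on a centroid gets that centroid's class: invert the
  # projection by least squares to construct such a feature vector
  cen1 <- fit$centroids[1, ]
  x_on <- fit$projection$center +
    as.numeric(qr.solve(t(fit$projection$rotation), cen1))
  expect_identical(as.character(predict(fit, matrix(x_on, 1))),
                   as.character(fit$cluster_to_class[1]))

  # separable data: predictions agree with a brute-force distance computation
  pred <- predict(fit, b$x)
  z <- project(fit$projection, b$x)
  brute <- apply(z, 1, function(p) {
    which.min(colSums((t(fit$centroids) - p)^2))
  })
  expect_identical(as.character(pred),
                   as.character(fit$cluster_to_class[brute]))
  expect_identical(as.character(pred), as.character(b$y))

  expect_error(predict(fit, b$x[, 1, drop = FALSE]), "dimensionality")
})

test_that("equidistant points resolve to the lowest cluster index", {
  fit <- structure(list(
    projection = structure(list(rotation = diag(2), center = c(0, 0),
                                method = "pca", ncomp = 2L,
                                explained_fraction = c(0.5, 0.5),
                                block_lengths = NULL, tol = NA_real_),
                           class = "cv_projection"),
    centroids = rbind(c(-1, 0), c(1, 0)),
    cluster_to_class = factor(c("b", "a"), levels = c("a", "b")),
    levels = c("a", "b"), train_scores = NULL, train_labels = NULL, seed = NULL
  ), class = "cv_clusterfit")
  # (0, 0) is exactly equidistant; cluster 1 wins, whose class is "b"
  expect_identical(as.character(predict(fit, matrix(c(0, 0), 1))), "b")
})

test_that("cluster-to-classes classification of separated blobs is perfect", {
  b <- make_blobs(n = 30, centers = rbind(c(0, 0, 0), c(7, 0, 0), c(0, 7, 0)),
                  sd = 0.6, seed = 10)
  fit <- fit_cluster_classifier(b$x, b$y, method = "lda", seed = 2, quiet = TRUE)
  m <- classification_metrics(b$y, predict(fit, b$x))
  expect_equal(m$f1, 100)
})

test_that("fit and predict are reproducible under a fixed seed", {
  ds <- tiny_dataset()
  inst <- build_instances(ds, k = 35)
  y <- factor(inst$cultivar)
  f1 <- fit_cluster_classifier(inst, y, method = "lda", seed = 99, quiet = TRUE)
  f2 <- fit_cluster_classifier(inst, y, method = "lda", seed = 99, quiet = TRUE)
  expect_identical(f1$centroids, f2$centroids)
  expect_identical(predict(f1, inst), predict(f2, inst))
})

test_that("feature relevance annotates sensor blocks with unit-norm components", {
  ds <- tiny_dataset()
  inst <- build_instances(ds, k = 35)
  fit <- fit_cluster_classifier(inst, factor(inst$cultivar), method = "lda",
                                seed = 1, quiet = TRUE)
  rel <- feature_relevance(fit)
  m <- sum(attr(inst, "block_lengths"))
  expect_identical(nrow(rel), m * fit$projection$ncomp)
  expect_identical(as.character(rel$sensor[rel$feature == 1]),
                   rep("CNP", fit$projection$ncomp))
  norms <- rel |>
    dplyr::group_by(component) |>
    dplyr::summarise(ss = sum(coefficient^2))
  expect_equal(norms$ss, rep(1, fit$projection$ncomp), tolerance = 1e-10)
  expect_identical(tidy(fit), rel)
  expect_identical(glance(fit)$n_components, fit$projection$ncomp)
})

test_that("comparator specifications carry the protocol defaults", {
  rf <- classifier_spec("rf")
  expect_equal(rf$hyperparameters$ntree, 100)
  expect_identical(rf$hyperparameters$criterion, "gini")
  expect_null(rf$hyperparameters$max_depth)  # unlimited depth
  svm <- classifier_spec("svm")
  expect_identical(svm$hyperparameters$kernel, "polynomial")
  expect_equal(svm$hyperparameters$degree, 6)
  rnn <- classifier_spec("rnn")
  expect_equal(rnn$hyperparameters$dropout, 0.6)
  expect_equal(rnn$hyperparameters$validation_split, 0.3)
  expect_identical(rnn$hyperparameters$output, "softmax")
  expect_error(classifier_spec("rf", bogus = 1), "unknown hyperparameter")
  expect_error(classifier_spec("knn"), "arg")
})

test_that("random-forest and SVM comparators classify separated blobs", {
  b <- make_blobs(n = 25, sd = 0.7, seed = 6)
  for (method in c("rf", "svm")) {
    fit <- fit_classifier(b$x, b$y, classifier_spec(method), seed = 1)
    acc <- mean(predict(fit, b$x) == b$y)
    expect_gt(acc, 0.95)
  }
  expect_error(fit_classifier(b$x, b$y, classifier_spec("rnn")),
               "no recurrent neural network backend")
})

test_that("models survive a serialization round trip", {
  b <- make_blobs(n = 15, seed = 12)
  fit <- fit_cluster_classifier(b$x, b$y, method = "lda", seed = 3, quiet = TRUE)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_equal(back$projection$rotation, fit$projection$rotation, tolerance = 1e-12)
  expect_identical(predict(back, b$x), predict(fit, b$x))
})
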