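#' One-vs-rest confusion counts
#'
#' For each class, the counts of true positives, false positives, false
#' negatives and true negatives of its one-vs-rest reduction; the four counts
#' sum to the number of instances for every class.
#'
#' @param truth,estimate Equal-length label vectors.
#' @param labels Class inventory; defaults to the union of levels/values.
#' @return A tibble with columns `class`, `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(truth, estimate, labels = NULL) {
  if (length(truth) == 0) abort("empty input")
  if (length(truth) != length(estimate)) abort("truth and estimate lengths differ")
  labels <- labels %||% sort(union(unique(as.character(truth)),
                                   unique(as.character(estimate))))
  truth <- factor(as.character(truth), levels = labels)
  estimate <- factor(as.character(estimate), levels = labels)
  n <- length(truth)
  purrr::map(labels, function(cl) {
    tp <- sum(truth == cl & estimate == cl)
    fp <- sum(truth != cl & estimate == cl)
    fn <- sum(truth == cl & estimate != cl)
    tibble::tibble(class = cl, tp = tp, fp = fp, fn = fn, tn = n - tp - fp - fn)
  }) |> purrr::list_rbind()
}

safe_ratio <- function(num, den) ifelse(den == 0, 0, num / den)

#' Macro-averaged classification metrics
#'
#' Per-class one-vs-rest recall `TP/(TP+FN)`, precision `TP/(TP+FP)` and
#' F1 `2TP/(2TP+FP+FN)` are macro-averaged with equal class weights; accuracy
#' is the fraction of correct predictions (the multiclass form of
#' `(TP+TN)/(TP+FP+TN+FN)`).  All four are reported as percentages.  A class
#' absent from `truth` has undefined recall; it is reported as 0 with a
#' warning.
#'
#' @inheritParams confusion_counts
#' @param per_class Return the per-class breakdown instead of macro averages.
#' @return A one-row tibble with `recall`, `precision`, `f1`, `accuracy` (in
#'   percent), or a per-class tibble when `per_class = TRUE`.
#' @export
#' @examples
#' classification_metrics(c("A", "A", "B", "B"), c("A", "B", "B", "B"))
classification_metrics <- function(truth, estimate, labels = NULL,
                                   per_class = FALSE) {
  cc <- confusion_counts(truth, estimate, labels)
  absent <- cc$class[cc$tp + cc$fn == 0]
  if (length(absent) > 0) {
    warn(paste0("class(es) absent from truth: ", paste(absent, collapse = ", "),
                "; their recall is reported as 0"))
  }
  per <- cc |>
    dplyr::mutate(
      recall = 100 * safe_ratio(.data$tp, .data$tp + .data$fn),
      precision = 100 * safe_ratio(.data$tp, .data$tp + .data$fp),
      f1 = 100 * safe_ratio(2 * .data$tp, 2 * .data$tp + .data$fp + .data$fn)
    )
  if (per_class) return(per)
  tibble::tibble(
    recall = mean(per$recall),
    precision = mean(per$precision),
    f1 = mean(per$f1),
    accuracy = 100 * mean(as.character(truth) == as.character(estimate))
  )
}

#' Majority-vote measurement-wise classification
#'
#' Aggregates scan-level predictions to measurement level: each group of
#' predictions sharing a measurement key is assigned its modal predicted
#' class (ties resolve to the lowest class index and are reported), and the
#' group is correct when the vote matches its true class.
#'
#' @param predictions A tibble with one row per scan-level prediction.
#' @param truth,estimate Column names (strings) of the true and predicted
#'   labels.
#' @param group Character vector of column names identifying a measurement.
#' @param quiet Suppress tie messages.
#' @return A tibble with one row per measurement (`group` columns, `n_scans`,
#'   `truth`, `vote`, `correct`) carrying the measurement-level accuracy (in
#'   percent) as attribute `"accuracy"`.
#' @export
#' @examples
#' p <- tibble::tibble(m = c(1, 1, 1, 2, 2), truth = c("A", "A", "A", "B", "B"),
#'                     pred = c("A", "A", "B", "B", "B"))
#' majority_vote(p, truth = "truth", estimate = "pred", group = "m")
majority_vote <- function(predictions, truth = "truth", estimate = "estimate",
                          group = c("cultivar", "electrode_id"), quiet = FALSE) {
  if (nrow(predictions) == 0) abort("empty input")
  levs <- levels(factor(predictions[[estimate]]))
  out <- predictions |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(
      n_scans = dplyr::n(),
      truth = as.character(.data[[truth]][1]),
      vote = {
        tab <- table(factor(.data[[estimate]], levels = levs))
        top <- names(tab)[tab == max(tab)]
        if (length(top) > 1 && !quiet) {
          inform(paste0("majority-vote tie between ", paste(top, collapse = ", "),
                        "; resolved to lowest class index (", top[1], ")"))
        }
        top[1]
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(correct = .data$truth == .data$vote)
  attr(out, "accuracy") <- 100 * mean(out$correct)
  out
}

split_indices <- function(instances, test_fraction, seed, split) {
  n <- nrow(instances)
  if (split == "instance") {
    n_test <- floor(n * test_fraction)
    test <- withr::with_seed(seed, sample.int(n, n_test))
  } else {
    key <- paste(instances$cultivar, instances$electrode_id)
    groups <- unique(key)
    n_test_g <- max(1L, floor(length(groups) * test_fraction))
    test_groups <- withr::with_seed(seed, sample(groups, n_test_g))
    test <- which(key %in% test_groups)
  }
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Repeated random-split evaluation
#'
#' The reference protocol: for each of `n_runs` runs, the instances are split
#' at random into a training portion and a test portion (30% by default), the
#' cross-sensor range statistics are refitted on the training portion only and
#' applied to both portions, the classifier is fitted on the training portion
#' and evaluated on the test portion, and per-run macro recall, precision, F1
#' and accuracy (plus the measurement-level majority-vote accuracy) are
#' recorded.  Reported summaries are arithmetic means over the runs.  Run `r`
#' uses seed `base_seed + r` for its split and its classifier, so a report is
#' reproducible from (`base_seed`, `n_runs`) alone.
#'
#' Splitting defaults to the instance (scan-triple) level, matching the
#' scan-as-instance protocol; `split = "measurement"` instead holds out whole
#' electrodes, so no electrode contributes to both portions.
#'
#' @param x A `cv_instances` tibble (see [build_instances()]) or a
#'   `cv_dataset`, which is preprocessed first with window `k`.
#' @param methods Character vector of method names, or a list of
#'   [classifier_spec()] objects.
#' @param n_runs Number of independent splits.
#' @param test_fraction Fraction of instances held out for testing.
#' @param base_seed Base seed for the per-run seeds.
#' @param k Subsampling window, used only when `x` is a raw dataset.
#' @param ablate Optional sensor name whose feature block is removed before
#'   evaluation.
#' @param split `"instance"` or `"measurement"`.
#' @return An object of class `cv_eval`: a list with `runs` (per-run tibble),
#'   `summary` (per-method means), `n_runs`, `test_fraction`, `base_seed`,
#'   `split`.
#' @export
repeated_evaluation <- function(x, methods = "lda_kmeans", n_runs = 100,
                                test_fraction = 0.3, base_seed = 1, k = 35,
                                ablate = NULL,
                                split = c("instance", "measurement")) {
  split <- match.arg(split)
  if (n_runs < 1) abort("n_runs must be at least 1")
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("test_fraction must be strictly between 0 and 1")
  }
  instances <- if (inherits(x, "cv_instances")) x else build_instances(x, k = k)
  if (!is.null(ablate)) instances <- ablate_sensor(instances, ablate)

  specs <- if (is.list(methods) && inherits(methods[[1]], "cv_spec")) {
    methods
  } else {
    purrr::map(methods, classifier_spec)
  }
  y_all <- factor(instances$cultivar)
  preprocessed <- isTRUE(attr(instances, "preprocessed"))

  runs <- purrr::map(specs, function(spec) {
    purrr::map(seq_len(n_runs), function(r) {
      seed_r <- base_seed + r
      idx <- split_indices(instances, test_fraction, seed_r, split)
      y_train <- y_all[idx$train]
      if (dplyr::n_distinct(y_train) < nlevels(y_all)) {
        warn(paste0("run ", r, ": a class is absent from the training split; ",
                    "run skipped"))
        return(NULL)
      }
      X <- if (preprocessed) {
        stats <- stats_from_instances(instances, idx$train)
        features_under_stats(instances, stats)
      } else {
        instance_matrix(instances)
      }
      fit <- fit_classifier(X[idx$train, , drop = FALSE], y_train, spec,
                            seed = seed_r)
      pred <- predict(fit, X[idx$test, , drop = FALSE])
      y_test <- y_all[idx$test]
      mets <- classification_metrics(y_test, pred, labels = levels(y_all))
      mv <- majority_vote(
        dplyr::mutate(instances[idx$test, c("cultivar", "electrode_id")],
                      truth = as.character(y_test), estimate = as.character(pred)),
        quiet = TRUE
      )
      dplyr::bind_cols(
        tibble::tibble(method = spec$method, run = r, seed = seed_r,
                       n_train = length(idx$train), n_test = length(idx$test)),
        mets,
        tibble::tibble(majority_accuracy = attr(mv, "accuracy"))
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  if (nrow(runs) == 0) abort("every run was skipped; no evaluable split found")
  summary <- runs |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(n_runs = dplyr::n(),
                     dplyr::across(c("recall", "precision", "f1", "accuracy",
                                     "majority_accuracy"), mean),
                     .groups = "drop")
  structure(
    list(runs = runs, summary = summary, n_runs = n_runs,
         test_fraction = test_fraction, base_seed = base_seed, split = split,
         ablate = ablate),
    class = "cv_eval"
  )
}

#' @export
print.cv_eval <- function(x, ...) {
  cat(sprintf("<cv_eval> %d run(s), test fraction %.2f, %s-level splits%s\n",
              x$n_runs, x$test_fraction, x$split,
              if (!is.null(x$ablate)) paste0(", ", x$ablate, " ablated") else ""))
  print(x$summary)
  invisible(x)
}

#' One-way ANOVA on monosaccharide sums
#'
#' Classical one-way analysis of variance on per-replicate glucose + fructose
#' sums across cultivars, the cross-check that cultivars genuinely differ in
#' soluble monosaccharide content.  Degenerate inputs are handled explicitly:
#' when the group means are identical the F statistic is 0 (and p = 1 when
#' additionally all values are constant).
#'
#' @param replicates A tibble with a `cultivar` column and either a `total`
#'   column or `glucose` and `fructose` columns (g/100 g, one row per
#'   replicate).
#' @return A one-row tibble: `statistic` (F), `df_between`, `df_within`,
#'   `p_value`.
#' @export
#' @examples
#' anova_monosaccharides(simulate_monosaccharide_replicates(seed = 1))
anova_monosaccharides <- function(replicates) {
  if (!"total" %in% names(replicates)) {
    if (!all(c("glucose", "fructose") %in% names(replicates))) {
      abort("replicates needs a 'total' column or 'glucose' and 'fructose' columns")
    }
    replicates$total <- replicates$glucose + replicates$fructose
  }
  g <- factor(replicates$cultivar)
  if (nlevels(g) < 2) abort("need at least 2 cultivars")
  if (any(tabulate(g) < 2)) abort("need at least 2 replicates per cultivar")
  y <- replicates$total

  gm <- tapply(y, g, mean)
  ssb <- sum(tabulate(g) * (gm - mean(y))^2)
  ssw <- sum((y - gm[as.integer(g)])^2)
  df1 <- nlevels(g) - 1L
  df2 <- length(y) - nlevels(g)
  eps <- .Machine$double.eps * max(1, sum(y^2))
  if (ssb <= eps) {
    return(tibble::tibble(statistic = 0, df_between = df1, df_within = df2,
                          p_value = 1))
  }
  if (ssw <= eps) {
    return(tibble::tibble(statistic = Inf, df_between = df1, df_within = df2,
                          p_value = 0))
  }
  f <- (ssb / df1) / (ssw / df2)
  tibble::tibble(statistic = f, df_between = df1, df_within = df2,
                 p_value = pf(f, df1, df2, lower.tail = FALSE))
}

#' Simulate replicate monosaccharide determinations
#'
#' Draws per-replicate glucose and fructose values from normal distributions
#' at each cultivar's reference mean and replicate standard deviation,
#' emulating the triplicate ion-chromatography determinations used for the
#' ANOVA cross-check.
#'
#' @param cultivars Tibble as from [tomato_cultivars()]; per-analyte `_sd`
#'   columns are used when present, otherwise `sd` applies to both analytes.
#' @param n_replicates Replicates per cultivar.
#' @param sd Fallback standard deviation (g/100 g).
#' @param seed Integer seed.
#' @return A tibble with columns `cultivar`, `replicate`, `glucose`,
#'   `fructose`, `total`.
#' @export
simulate_monosaccharide_replicates <- function(cultivars = tomato_cultivars(),
                                               n_replicates = 3, sd = 0.05,
                                               seed = 1) {
  g_sd <- cultivars$glucose_sd %||% rep(sd, nrow(cultivars))
  f_sd <- cultivars$fructose_sd %||% rep(sd, nrow(cultivars))
  withr::with_seed(seed, {
    purrr::map(seq_len(nrow(cultivars)), function(i) {
      tibble::tibble(
        cultivar = cultivars$cultivar[i],
        replicate = seq_len(n_replicates),
        glucose = rnorm(n_replicates, cultivars$glucose[i], g_sd[i]),
        fructose = rnorm(n_replicates, cultivars$fructose[i], f_sd[i])
      )
    }) |> purrr::list_rbind() |>
      dplyr::mutate(total = .data$glucose + .data$fructose)
  })
}
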