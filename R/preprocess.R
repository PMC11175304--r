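#' Drop the potential axis: current vs sequence number
#'
#' A cyclic-voltammetry scan is not a single-valued function of potential
#' (forward and backward branches differ), so scans are represented as current
#' versus sequence number — the index of a data point within the acquisition
#' vector — before any further processing.  Acquisition order is preserved.
#'
#' @param dataset A `cv_dataset`.
#' @return The same tibble without the `potential` list-column.
#' @export
to_sequence <- function(dataset) {
  dplyr::select(tibble::as_tibble(dataset), -dplyr::any_of("potential"))
}

# Affine map sending x onto the range [lo, hi].
rescale_to <- function(x, lo, hi, what = "scan") {
  r <- range(x)
  if (r[2] <= r[1]) {
    abort(paste0("degenerate ", what, ": max equals min, cannot normalize"))
  }
  (hi - lo) * (x - r[1]) / (r[2] - r[1]) + lo
}

#' Normalize every scan of a measurement to the range of its first scan
#'
#' The amplitude of the measured currents decays from scan to scan (diffusion
#' and sensing-layer depletion), but each scan carries the same compositional
#' information.  Every scan `s` of a measurement is therefore linearly mapped
#' onto the current range of the measurement's first scan `f`:
#' `sN = (max(f) - min(f)) * (s - min(s)) / (max(s) - min(s)) + min(f)`,
#' where `min(s)`/`max(s)` are the extrema of the scan being normalized.  The
#' first scan maps to itself; every output scan has exactly the first scan's
#' extrema.
#'
#' @param x Either a list of numeric current vectors, ordered so the first
#'   element is the measurement's first scan, or a `cv_dataset` / sequence
#'   tibble, in which case the map is applied per measurement (ordered by
#'   `scan_index`, the first scan being `scan_index == 0`).
#' @return An object of the same shape with normalized currents.
#' @export
#' @examples
#' normalize_to_first(list(c(10, 20), c(0, 1, 2)))
normalize_to_first <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    if (length(x) < 1) abort("need at least one scan")
    f <- range(x[[1]])
    if (f[2] <= f[1]) abort("degenerate scan: the first scan is constant")
    return(purrr::imap(x, function(s, i) {
      rescale_to(s, f[1], f[2], what = paste0("scan ", i - 1))
    }))
  }
  x |>
    dplyr::group_by(.data$measurement_id) |>
    dplyr::arrange(.data$scan_index, .by_group = TRUE) |>
    dplyr::mutate(current = normalize_to_first(.data$current)) |>
    dplyr::ungroup()
}

#' Training-set current range per sensor
#'
#' Computes the global minimum and maximum current per sensor over a set of
#' (first-stage-normalized) scans.  These are the fitted parameters of the
#' cross-sensor range equalization; they must come from training data only so
#' that test scans never leak into the transformation.
#'
#' @param dataset A `cv_dataset` or sequence tibble of training scans.
#' @return A tibble with columns `sensor`, `min`, `max` (uA).
#' @export
fit_range_stats <- function(dataset) {
  if (nrow(dataset) == 0) abort("missing-sensor error: no training scans at all")
  stats <- dataset |>
    dplyr::group_by(.data$sensor) |>
    dplyr::summarise(min = min(purrr::map_dbl(.data$current, min)),
                     max = max(purrr::map_dbl(.data$current, max)),
                     .groups = "drop")
  if (any(stats$max <= stats$min)) {
    abort(paste0("degenerate-stats error: max equals min for sensor ",
                 paste(stats$sensor[stats$max <= stats$min], collapse = ", ")))
  }
  stats
}

# Affine coefficients mapping sensor ranges onto the reference sensor range.
equalization_coef <- function(stats, reference = "CNP") {
  if (!reference %in% stats$sensor) {
    abort(paste0("missing-sensor error: reference sensor ", reference,
                 " absent from range stats"))
  }
  if (any(stats$max <= stats$min)) {
    abort("degenerate-stats error: range stats with max <= min")
  }
  ref <- stats[stats$sensor == reference, ]
  stats |>
    dplyr::mutate(
      a = ifelse(.data$sensor == reference, 1,
                 (ref$max - ref$min) / (.data$max - .data$min)),
      b = ifelse(.data$sensor == reference, 0,
                 ref$min - (ref$max - ref$min) / (.data$max - .data$min) * .data$min)
    ) |>
    dplyr::select("sensor", "a", "b")
}

#' Equalize cross-sensor current ranges
#'
#' Scans from the non-reference sensors are affinely mapped onto the training
#' set range of the reference sensor (CNP by default):
#' `sN = (max(CNP) - min(CNP)) * (s - min(GNP)) / (max(GNP) - min(GNP)) + min(CNP)`
#' and analogously for PEDOT.  Reference-sensor scans pass through unchanged.
#' Because the map is fixed by training-set statistics, an individual
#' transformed test scan's range need not equal the reference range exactly;
#' over the training set the global extrema match exactly.
#'
#' @param dataset A `cv_dataset` or sequence tibble.
#' @param stats Range statistics from [fit_range_stats()] (training set only).
#' @param reference Reference sensor name, default `"CNP"`.
#' @return The tibble with currents mapped.
#' @export
equalize_ranges <- function(dataset, stats, reference = "CNP") {
  coef <- equalization_coef(stats, reference)
  missing <- setdiff(unique(dataset$sensor), coef$sensor)
  if (length(missing) > 0) {
    abort(paste0("missing-sensor error: no range stats for sensor(s) ",
                 paste(missing, collapse = ", ")))
  }
  dataset |>
    dplyr::left_join(coef, by = "sensor") |>
    dplyr::mutate(current = purrr::pmap(list(.data$current, .data$a, .data$b),
                                        function(x, a, b) a * x + b)) |>
    dplyr::select(-"a", -"b")
}

#' Window-average subsampling
#'
#' Averages values over consecutive disjoint windows of length `k`, reducing a
#' length-`n` vector to `floor(n / k)` points; the trailing `n %% k` points
#' are discarded.  With `k = 1` this is the identity.
#'
#' @param x Numeric vector.
#' @param k Window length, a positive integer not exceeding `length(x)`.
#' @return Numeric vector of length `floor(length(x) / k)`.
#' @export
#' @examples
#' subsample_mean(c(1, 2, 3, 4, 5, 6), 2)
subsample_mean <- function(x, k) {
  n <- length(x)
  k <- as.integer(k)
  if (k < 1) abort("window length k must be at least 1")
  if (k > n) abort(paste0("window-too-long error: k = ", k,
                          " exceeds scan length n = ", n))
  m <- n %/% k
  colMeans(matrix(x[seq_len(m * k)], nrow = k))
}

#' Build concatenated feature instances
#'
#' Runs the full preprocessing pipeline: sequence conversion, per-measurement
#' normalization to the first scan, grouping of scans into cross-sensor
#' triples keyed by (cultivar, electrode slot, scan index), range
#' equalization against training statistics, window-average subsampling with
#' window `k`, and concatenation of the per-sensor blocks in the fixed order
#' CNP, GNP, PEDOT.  One instance is produced per triple (total scans / number
#' of sensors).
#'
#' The returned object keeps the unequalized per-sensor blocks and each source
#' scan's full-resolution normalized current range as attributes, so range
#' statistics can be refitted on any training subset (see
#' [repeated_evaluation()]) without reprocessing the raw scans: equalization
#' is affine and commutes with window averaging.
#'
#' @param dataset A `cv_dataset` in which every (cultivar, electrode, scan
#'   index) key has exactly one scan per sensor.
#' @param k Subsampling window length (default 35).
#' @param stats Optional pre-fitted range statistics; by default they are
#'   fitted on all scans of `dataset`.  For leakage-free evaluation fit them
#'   on the training portion only.
#' @return A tibble of class `cv_instances` with columns `cultivar`,
#'   `electrode_id`, `scan_index` and a matrix column `features`; attributes
#'   `block_lengths`, `range_stats`, `k`.
#' @export
build_instances <- function(dataset, k = 35, stats = NULL) {
  seq_ds <- to_sequence(dataset) |> normalize_to_first()

  sensors <- intersect(SENSOR_LEVELS, unique(seq_ds$sensor))
  long <- seq_ds |>
    dplyr::mutate(
      rmin = purrr::map_dbl(.data$current, min),
      rmax = purrr::map_dbl(.data$current, max),
      block = purrr::map(.data$current, subsample_mean, k = k)
    ) |>
    dplyr::select("cultivar", "electrode_id", "scan_index", "sensor",
                  "block", "rmin", "rmax")

  dup <- long |>
    dplyr::count(.data$cultivar, .data$electrode_id, .data$scan_index, .data$sensor) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("pairing error: multiple scans for key (",
                 dup$cultivar[1], ", ", dup$electrode_id[1], ", scan ",
                 dup$scan_index[1], ", ", dup$sensor[1], ")"))
  }
  counts <- long |>
    dplyr::count(.data$cultivar, .data$electrode_id, .data$scan_index) |>
    dplyr::filter(.data$n != length(sensors))
  if (nrow(counts) > 0) {
    abort(paste0("pairing error: key (", counts$cultivar[1], ", ",
                 counts$electrode_id[1], ", scan ", counts$scan_index[1],
                 ") lacks a scan for some sensor"))
  }

  long <- dplyr::arrange(long, .data$cultivar, .data$electrode_id,
                         .data$scan_index, match(.data$sensor, sensors))
  keys <- dplyr::distinct(long, .data$cultivar, .data$electrode_id, .data$scan_index)

  raw_blocks <- list()
  scan_ranges <- list()
  for (s in sensors) {
    sub <- long[long$sensor == s, ]
    lens <- unique(lengths(sub$block))
    if (length(lens) != 1) {
      abort(paste0("scans of sensor ", s, " have differing lengths after subsampling"))
    }
    raw_blocks[[s]] <- do.call(rbind, sub$block)
    scan_ranges[[s]] <- cbind(min = sub$rmin, max = sub$rmax)
  }

  if (is.null(stats)) {
    stats <- tibble::tibble(
      sensor = sensors,
      min = purrr::map_dbl(sensors, ~ min(scan_ranges[[.x]][, "min"])),
      max = purrr::map_dbl(sensors, ~ max(scan_ranges[[.x]][, "max"]))
    )
  }

  inst <- keys
  inst$features <- assemble_features(raw_blocks, stats,
                                     reference = reference_sensor(sensors))
  structure(
    inst,
    class = c("cv_instances", class(inst)),
    block_lengths = purrr::map_int(raw_blocks, ncol),
    raw_blocks = raw_blocks,
    scan_ranges = scan_ranges,
    range_stats = stats,
    k = k,
    preprocessed = TRUE
  )
}

reference_sensor <- function(sensors) if ("CNP" %in% sensors) "CNP" else sensors[1]

# Concatenate per-sensor block matrices after applying the equalization
# affine map implied by `stats`.
assemble_features <- function(raw_blocks, stats, reference) {
  coef <- equalization_coef(stats, reference)
  blocks <- purrr::imap(raw_blocks, function(m, s) {
    cf <- coef[coef$sensor == s, ]
    if (nrow(cf) != 1) {
      abort(paste0("missing-sensor error: no range stats for sensor ", s))
    }
    cf$a * m + cf$b
  })
  do.call(cbind, unname(blocks))
}

# Range stats recomputed from a subset of instance rows, using the cached
# full-resolution normalized scan extrema.
stats_from_instances <- function(instances, rows) {
  ranges <- attr(instances, "scan_ranges")
  tibble::tibble(
    sensor = names(ranges),
    min = purrr::map_dbl(ranges, ~ min(.x[rows, "min"])),
    max = purrr::map_dbl(ranges, ~ max(.x[rows, "max"]))
  )
}

# Rebuild the concatenated feature matrix under new range stats.
features_under_stats <- function(instances, stats) {
  if (!isTRUE(attr(instances, "preprocessed"))) {
    return(instance_matrix(instances))
  }
  assemble_features(attr(instances, "raw_blocks"), stats,
                    reference = reference_sensor(names(attr(instances, "raw_blocks"))))
}

#' Extract the feature matrix of an instance set
#'
#' @param instances A `cv_instances` tibble.
#' @return A numeric matrix, instances by features.
#' @export
instance_matrix <- function(instances) {
  m <- instances$features
  dimnames(m) <- NULL
  m
}

#' Remove one sensor's feature block
#'
#' Drops the named sensor's block from every concatenated feature vector and
#' updates the block-length metadata, so downstream fitting (including
#' per-split range-statistic refits, which simply skip the removed sensor)
#' proceeds unchanged.  Used to probe the classifier's reliance on a single
#' sensor, e.g. excluding the ascorbic-acid-sensitive PEDOT block to test
#' sugar-only separability.
#'
#' @param instances A `cv_instances` tibble.
#' @param sensor Sensor block to remove (`"CNP"`, `"GNP"` or `"PEDOT"`).
#' @return A `cv_instances` tibble with the reduced feature vectors.
#' @export
ablate_sensor <- function(instances, sensor) {
  bl <- attr(instances, "block_lengths")
  if (!sensor %in% SENSOR_LEVELS) {
    abort(paste0("unknown sensor '", sensor, "'; allowed: ",
                 paste(SENSOR_LEVELS, collapse = ", ")))
  }
  if (!sensor %in% names(bl)) {
    abort(paste0("sensor ", sensor, " not present in these instances"))
  }
  keep <- setdiff(names(bl), sensor)
  if (length(keep) == 0) {
    abort("ablating would leave an empty feature set")
  }
  raw_blocks <- attr(instances, "raw_blocks")[keep]
  scan_ranges <- attr(instances, "scan_ranges")[keep]
  stats <- attr(instances, "range_stats")
  stats <- stats[stats$sensor %in% keep, ]

  out <- dplyr::select(tibble::as_tibble(instances), -"features")
  out$features <- assemble_features(raw_blocks, stats,
                                    reference = reference_sensor(keep))
  structure(
    out,
    class = c("cv_instances", class(out)),
    block_lengths = bl[keep],
    raw_blocks = raw_blocks,
    scan_ranges = scan_ranges,
    range_stats = stats,
    k = attr(instances, "k"),
    preprocessed = attr(instances, "preprocessed")
  )
}

#' Build unpreprocessed baseline instances
#'
#' The no-preprocessing baseline: raw current sequences (no normalization, no
#' range equalization, no subsampling) are truncated to each sensor's shortest
#' scan length so the design matrix is rectangular, then concatenated in the
#' fixed sensor order.  Used to contrast classifier performance with and
#' without the preprocessing stage.
#'
#' @param dataset A `cv_dataset`.
#' @return A `cv_instances` tibble whose per-split evaluation skips range
#'   refitting (there is nothing fitted to refit).
#' @export
build_raw_instances <- function(dataset) {
  seq_ds <- to_sequence(dataset)
  sensors <- intersect(SENSOR_LEVELS, unique(seq_ds$sensor))
  long <- seq_ds |>
    dplyr::select("cultivar", "electrode_id", "scan_index", "sensor", "current") |>
    dplyr::arrange(.data$cultivar, .data$electrode_id, .data$scan_index,
                   match(.data$sensor, sensors))
  keys <- dplyr::distinct(long, .data$cultivar, .data$electrode_id, .data$scan_index)
  blocks <- purrr::map(sensors, function(s) {
    sub <- long[long$sensor == s, ]
    if (nrow(sub) != nrow(keys)) {
      abort(paste0("pairing error: sensor ", s, " does not cover every key"))
    }
    len <- min(lengths(sub$current))
    do.call(rbind, purrr::map(sub$current, ~ .x[seq_len(len)]))
  })
  names(blocks) <- sensors
  inst <- keys
  inst$features <- do.call(cbind, unname(blocks))
  structure(
    inst,
    class = c("cv_instances", class(inst)),
    block_lengths = purrr::map_int(blocks, ncol),
    range_stats = NULL,
    k = 1,
    preprocessed = FALSE
  )
}

#' @export
print.cv_instances <- function(x, ...) {
  bl <- attr(x, "block_lengths")
  cat(sprintf("<cv_instances> %d instances x %d features (%s)\n",
              nrow(x), sum(bl),
              paste(sprintf("%s:%d", names(bl), bl), collapse = ", ")))
  NextMethod()
}
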