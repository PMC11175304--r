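test_that("normalization maps every scan onto the first scan's range", {
  # hand evaluation: f spans [10, 20]; s = (0, 1, 2) -> (10, 15, 20)
  out <- normalize_to_first(list(c(10, 20), c(0, 1, 2)))
  expect_equal(out[[2]], c(10, 15, 20))
  # the first scan is a fixed point of the map
  f <- c(3, 1, 4, 1, 5)
  expect_identical(normalize_to_first(list(f))[[1]], f)

  # property: min/max of every output scan equal the first scan's exactly
  withr::with_seed(1, {
    for (rep in 1:10) {
      scans <- purrr::map(1:4, ~ rnorm(50, sd = runif(1, 0.1, 10)))
      out <- normalize_to_first(scans)
      for (s in out) {
        expect_equal(min(s), min(scans[[1]]), tolerance = 1e-9)
        expect_equal(max(s), max(scans[[1]]), tolerance = 1e-9)
      }
    }
  })

  expect_error(normalize_to_first(list(c(1, 2), c(5, 5, 5))), "degenerate")
  expect_error(normalize_to_first(list(c(7, 7))), "degenerate")
})

test_that("dataset-level normalization uses each measurement's first scan", {
  ds <- tiny_dataset(scans_per_electrode = 3, electrodes_per_condition = 1)
  norm <- normalize_to_first(to_sequence(ds))
  ranges <- norm |>
    dplyr::group_by(measurement_id) |>
    dplyr::summarise(
      spread_min = diff(range(purrr::map_dbl(current, min))),
      spread_max = diff(range(purrr::map_dbl(current, max)))
    )
  expect_lt(max(ranges$spread_min), 1e-9)
  expect_lt(max(ranges$spread_max), 1e-9)
})

test_that("range statistics are the training-set extrema per sensor", {
  mk <- function(sensor, ...) {
    vals <- list(...)
    tibble::tibble(measurement_id = paste0(sensor, seq_along(vals)),
                   sensor = sensor, cultivar = "x", electrode_id = "e1",
                   scan_index = 0L, current = vals)
  }
  ds <- dplyr::bind_rows(mk("CNP", 0:5, 2:9), mk("GNP", c(1, 3)))
  st <- fit_range_stats(ds)
  expect_equal(st$min[st$sensor == "CNP"], 0)
  expect_equal(st$max[st$sensor == "CNP"], 9)
  expect_equal(st$max[st$sensor == "GNP"], 3)  # single scan: its own extrema

  # growing the training set can only widen the interval
  widened <- dplyr::bind_rows(ds, mk("CNP", c(-5, 20)))
  st2 <- fit_range_stats(widened)
  expect_lte(st2$min[st2$sensor == "CNP"], st$min[st$sensor == "CNP"])
  expect_gte(st2$max[st2$sensor == "CNP"], st$max[st$sensor == "CNP"])

  expect_error(fit_range_stats(ds[0, ]), "missing-sensor")
  expect_error(fit_range_stats(mk("CNP", c(2, 2))), "degenerate-stats")
})

test_that("range equalization maps sensor envelopes onto the reference range", {
  stats <- tibble::tibble(sensor = c("CNP", "GNP"), min = c(0, 0), max = c(10, 5))
  ds <- tibble::tibble(measurement_id = c("a", "b"), sensor = c("GNP", "CNP"),
                       cultivar = "x", electrode_id = "e1", scan_index = 0L,
                       current = list(c(0, 2.5, 5), c(1, 2, 3)))
  out <- equalize_ranges(ds, stats)
  expect_equal(out$current[[1]], c(0, 5, 10))  # hand evaluation of the affine map
  expect_identical(out$current[[2]], c(1, 2, 3))  # reference sensor unchanged

  degenerate <- tibble::tibble(sensor = c("CNP", "GNP"), min = c(0, 2), max = c(10, 2))
  expect_error(equalize_ranges(ds, degenerate), "degenerate-stats")
  expect_error(equalize_ranges(ds, stats[stats$sensor == "GNP", ]),
               "missing-sensor")
})

test_that("equalizing the training set makes global extrema match the reference exactly", {
  ds <- tiny_dataset() |> to_sequence() |> normalize_to_first()
  stats <- fit_range_stats(ds)
  eq <- equalize_ranges(ds, stats)
  st2 <- fit_range_stats(eq)
  ref <- stats[stats$sensor == "CNP", ]
  for (s in c("CNP", "GNP", "PEDOT")) {
    expect_equal(st2$min[st2$sensor == s], ref$min)
    expect_equal(st2$max[st2$sensor == s], ref$max)
  }
})

test_that("window-average subsampling has floor(n/k) output and drops the remainder", {
  expect_equal(subsample_mean(c(1, 2, 3, 4, 5, 6), 2), c(1.5, 3.5, 5.5))
  x <- rnorm(37)
  expect_identical(subsample_mean(x, 1), x)        # identity window
  expect_length(subsample_mean(x, 5), 7L)          # 37 %/% 5, remainder dropped
  expect_equal(subsample_mean(x, 5)[1], mean(x[1:5]))
  expect_length(subsample_mean(rnorm(28000), 35), 800L)
  expect_error(subsample_mean(x, 38), "window-too-long")
  expect_error(subsample_mean(x, 0), "at least 1")
})

test_that("subsampling commutes with affine maps", {
  withr::with_seed(3, {
    for (rep in 1:5) {
      x <- rnorm(100)
      a <- runif(1, -3, 3); b <- runif(1, -5, 5)
      expect_equal(subsample_mean(a * x + b, 7), a * subsample_mean(x, 7) + b,
                   tolerance = 1e-12)
    }
  })
})

test_that("instance building concatenates CNP, GNP, PEDOT blocks per triple", {
  ds <- tiny_dataset()
  inst <- build_instances(ds, k = 35)
  expect_identical(nrow(inst), nrow(ds) %/% 3L)
  bl <- attr(inst, "block_lengths")
  expect_identical(bl, c(CNP = 8L, GNP = 6L, PEDOT = 6L))  # floor(points/35)
  expect_identical(ncol(inst$features), 20L)
  expect_identical(names(bl), c("CNP", "GNP", "PEDOT"))
})

test_that("instance building is invariant to input row order", {
  ds <- tiny_dataset(scans_per_electrode = 2)
  a <- build_instances(ds, k = 35)
  shuffled <- structure(ds[withr::with_seed(9, sample(nrow(ds))), ],
                        class = class(ds))
  b <- build_instances(shuffled, k = 35)
  expect_equal(tibble::as_tibble(a), tibble::as_tibble(b))
})

test_that("instance building agrees with the explicit dataset-level pipeline", {
  # independent route: normalize, fit stats, equalize, subsample, cbind by hand
  ds <- tiny_dataset(scans_per_electrode = 2, electrodes_per_condition = 1)
  norm <- normalize_to_first(to_sequence(ds))
  eq <- equalize_ranges(norm, fit_range_stats(norm))
  manual <- eq |>
    dplyr::mutate(block = purrr::map(current, subsample_mean, k = 35)) |>
    dplyr::arrange(cultivar, electrode_id, scan_index,
                   match(sensor, c("CNP", "GNP", "PEDOT")))
  keys <- dplyr::distinct(manual, cultivar, electrode_id, scan_index)
  expected <- t(sapply(seq_len(nrow(keys)), function(i) {
    sel <- manual$cultivar == keys$cultivar[i] &
      manual$electrode_id == keys$electrode_id[i] &
      manual$scan_index == keys$scan_index[i]
    unlist(manual$block[sel])
  }))
  inst <- build_instances(ds, k = 35)
  expect_equal(unname(instance_matrix(inst)), unname(expected), tolerance = 1e-12)
})

test_that("missing sensors in a triple raise a pairing error", {
  ds <- tiny_dataset(scans_per_electrode = 2, electrodes_per_condition = 1)
  drop_one <- structure(ds[!(ds$sensor == "GNP" & ds$cultivar == "perino"), ],
                        class = class(ds))
  expect_error(build_instances(drop_one, k = 35), "pairing error")
})

test_that("raw baseline instances truncate to a common length and skip normalization", {
  ds <- tiny_dataset(scans_per_electrode = 2, electrodes_per_condition = 1)
  raw <- build_raw_instances(ds)
  expect_identical(sum(attr(raw, "block_lengths")), 280L + 210L + 210L)
  expect_false(isTRUE(attr(raw, "preprocessed")))
  # first CNP feature is the raw first current sample of the CNP scan
  first_key <- tibble::as_tibble(raw)[1, ]
  src <- ds[ds$sensor == "CNP" & ds$cultivar == first_key$cultivar &
              ds$electrode_id == first_key$electrode_id &
              ds$scan_index == first_key$scan_index, ]
  expect_identical(raw$features[1, 1], src$current[[1]][1])
})
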