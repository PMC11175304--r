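# Small-scale fixtures shared across test files.  Scan lengths are shrunk so
# each file runs in seconds; the full-scale defaults are exercised in
# test-acceptance.R.

tiny_sensors <- function(points = c(280L, 210L, 210L)) {
  se <- default_sensors()
  se$points <- points
  se
}

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(sensors = tiny_sensors(), scans_per_electrode = 3,
         electrodes_per_condition = 2, noise_sd = 0.3, seed = 42),
    list(...)
  )
  do.call(generator_config, args)
}

tiny_dataset <- function(...) generate_dataset(tiny_config(...))

# Gaussian class blobs for classifier tests: n per class around each row of
# `centers` (classes x features), labelled a, b, c, ...
make_blobs <- function(n = 20, centers = rbind(c(0, 0), c(6, 0), c(0, 6)),
                       sd = 0.5, seed = 1) {
  withr::with_seed(seed, {
    K <- nrow(centers)
    x <- do.call(rbind, lapply(seq_len(K), function(k) {
      matrix(rnorm(n * ncol(centers), sd = sd), n) +
        matrix(centers[k, ], n, ncol(centers), byrow = TRUE)
    }))
    list(x = x, y = factor(rep(letters[seq_len(K)], each = n)))
  })
}

# A hand-built two-measurement dataset with odd scan lengths, for I/O tests
# that do not go through the generator.
manual_dataset <- function(points_per_scan = 5, n_scans = 2) {
  rows <- tidyr::expand_grid(sensor = c("CNP", "GNP", "PEDOT"),
                             scan_index = seq_len(n_scans) - 1L)
  out <- tibble::tibble(
    measurement_id = paste("perino", rows$sensor, "e1", sep = "_"),
    sensor = rows$sensor,
    cultivar = "perino",
    electrode_id = "e1",
    scan_index = rows$scan_index,
    potential = purrr::map(rows$scan_index,
                           ~ seq(0, 1, length.out = points_per_scan)),
    current = purrr::map(rows$scan_index,
                         ~ seq(1, 2, length.out = points_per_scan) + .x)
  )
  structure(out, class = c("cv_dataset", class(out)))
}
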