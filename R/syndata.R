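#' Triangular potential sweep for a sensor
#'
#' Builds the shared potential grid of one cyclic-voltammetry scan: a forward
#' branch from the window's lower bound up to the upper bound, followed by a
#' backward branch returning to the lower bound.  The upper bound is attained
#' exactly once (single turnaround) and both ends sit on the lower bound.
#'
#' @param sensor_spec One row of the sensor table (see [default_sensors()]).
#' @return Numeric vector of potentials, V, of length `sensor_spec$points`.
#' @export
potential_grid <- function(sensor_spec) {
  n <- sensor_spec$points
  nf <- n %/% 2L
  fwd <- seq(sensor_spec$v_min, sensor_spec$v_max, length.out = nf)
  bwd <- seq(sensor_spec$v_max, sensor_spec$v_min, length.out = n - nf + 1L)[-1L]
  c(fwd, bwd)
}

#' Generate one synthetic cyclic-voltammetry scan
#'
#' The signal model is a Gaussian oxidation peak on a sloped linear baseline
#' with a constant capacitive offset (positive on the forward branch, negative
#' on the backward branch, which guarantees hysteresis), additive Gaussian
#' noise, and power-law scan-to-scan amplitude decay.  The forward-branch peak
#' height is
#' `sensitivity * analyte_load * electrode_factor * (1 + scan_index)^(-decay_exponent)`;
#' the backward branch carries a displaced, attenuated counterpart of the peak.
#' The analyte load is glucose + fructose (g/100 g) for the CNP and GNP
#' sensors and the ascorbic-acid loading (a.u.) for PEDOT.
#'
#' Noise is drawn from the calling R session's random number generator; seed
#' it (or use [generate_dataset()], which seeds everything) for reproducible
#' scans.
#'
#' @param config A [generator_config()].
#' @param sensor Sensor name, one of `"CNP"`, `"GNP"`, `"PEDOT"`.
#' @param cultivar Cultivar name present in `config$cultivars`.
#' @param scan_index 0-based scan index within its measurement.
#' @param electrode_factor Positive multiplicative electrode gain.
#' @param measurement_id,electrode_id Optional provenance identifiers.
#' @return A one-row tibble with columns `measurement_id`, `sensor`,
#'   `cultivar`, `electrode_id`, `scan_index` and list-columns `potential`
#'   (V) and `current` (uA).
#' @export
#' @examples
#' cfg <- generator_config(noise_sd = 0)
#' scan <- generate_scan(cfg, "CNP", "perino")
#' length(scan$current[[1]])
generate_scan <- function(config, sensor, cultivar, scan_index = 0L,
                          electrode_factor = 1,
                          measurement_id = NULL, electrode_id = "e1") {
  validate_config(config)
  if (scan_index < 0) abort("scan_index must be >= 0")
  if (electrode_factor <= 0) abort("electrode_factor must be > 0")
  spec <- config$sensors[config$sensors$sensor == sensor, ]
  if (nrow(spec) != 1) {
    abort(paste0("unknown sensor '", sensor, "'; allowed: ",
                 paste(config$sensors$sensor, collapse = ", ")))
  }
  cu <- config$cultivars[config$cultivars$cultivar == cultivar, ]
  if (nrow(cu) != 1) {
    abort(paste0("unknown cultivar '", cultivar, "'"))
  }

  v <- potential_grid(spec)
  n <- length(v)
  nf <- spec$points %/% 2L
  branch_fwd <- seq_len(n) <= nf

  amp <- spec$sensitivity * analyte_load(sensor, cu) * electrode_factor *
    (1 + scan_index)^(-config$decay_exponent)
  peak <- function(center) amp * exp(-(v - center)^2 / (2 * spec$peak_width^2))

  current <- config$baseline_slope * (v - spec$v_min) +
    ifelse(branch_fwd, config$capacitive, -config$capacitive) +
    ifelse(branch_fwd, peak(spec$peak_center),
           config$hysteresis_atten * peak(spec$peak_center + config$hysteresis_shift))
  if (config$noise_sd > 0) current <- current + rnorm(n, 0, config$noise_sd)

  tibble::tibble(
    measurement_id = measurement_id %||% paste(cultivar, sensor, electrode_id, sep = "_"),
    sensor = sensor,
    cultivar = cultivar,
    electrode_id = electrode_id,
    scan_index = as.integer(scan_index),
    potential = list(v),
    current = list(current)
  )
}

#' Generate a full synthetic acquisition
#'
#' Emulates the acquisition protocol: for every cultivar, sensor and electrode
#' slot, a fresh disposable electrode records `scans_per_electrode` consecutive
#' scans of one sample aliquot (one *measurement*), after which the electrode
#' is discarded.  Each electrode draws its multiplicative gain once (lognormal
#' around 1 with log-sd `electrode_sd`).  Measurements are emitted in an order
#' randomized by the seeded generator, and the same configuration and seed
#' reproduce the dataset exactly.
#'
#' With the defaults (3 cultivars x 3 sensors x 6 electrodes x 20 scans) the
#' dataset holds 1080 scans in 54 measurements.
#'
#' @param config A [generator_config()].
#' @return A tibble of class `cv_dataset`, one row per scan, with columns
#'   `measurement_id`, `sensor`, `cultivar`, `electrode_id`, `scan_index` and
#'   list-columns `potential`, `current`.  The configuration is attached as
#'   attribute `"config"`.
#' @export
#' @examples
#' cfg <- generator_config(scans_per_electrode = 2, electrodes_per_condition = 1,
#'                         sensors = dplyr::mutate(default_sensors(), points = 70L))
#' nrow(generate_dataset(cfg))
generate_dataset <- function(config = generator_config()) {
  validate_config(config)
  withr::with_seed(config$seed, {
    grid <- tidyr::expand_grid(
      cultivar = config$cultivars$cultivar,
      sensor = config$sensors$sensor,
      electrode = seq_len(config$electrodes_per_condition)
    )
    # one gain per physical electrode, drawn before any scan noise
    grid$gain <- exp(rnorm(nrow(grid), 0, config$electrode_sd))

    measurements <- purrr::pmap(grid, function(cultivar, sensor, electrode, gain) {
      eid <- paste0("e", electrode)
      mid <- paste(cultivar, sensor, eid, sep = "_")
      purrr::map(seq_len(config$scans_per_electrode) - 1L, function(i) {
        generate_scan(config, sensor, cultivar, scan_index = i,
                      electrode_factor = gain,
                      measurement_id = mid, electrode_id = eid)
      }) |> purrr::list_rbind()
    })

    out <- purrr::list_rbind(measurements[sample(length(measurements))])
  })
  structure(out, class = c("cv_dataset", class(out)), config = config)
}

#' @export
print.cv_dataset <- function(x, ...) {
  cat(sprintf("<cv_dataset> %d scans, %d measurements, %d cultivars, %d sensors\n",
              nrow(x), dplyr::n_distinct(x$measurement_id),
              dplyr::n_distinct(x$cultivar), dplyr::n_distinct(x$sensor)))
  NextMethod()
}
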