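#' Reference cultivar composition
#'
#' Glucose and fructose concentrations (g/100 g, mean and standard deviation
#' of three replicate ion-chromatography determinations) for the three tomato
#' puree cultivars, together with the ascorbic-acid loading used by the
#' synthetic generator.  Ascorbic acid was not quantified by the reference
#' technique, so its per-cultivar loadings are synthetic placeholders in
#' arbitrary units, chosen to be class-separating (the conducting-polymer
#' sensor is the most discriminating one in this system) and exposed here so
#' they can be overridden.
#'
#' @return A tibble with columns `cultivar`, `glucose`, `glucose_sd`,
#'   `fructose`, `fructose_sd` (g/100 g) and `ascorbic` (arbitrary units).
#' @export
#' @examples
#' tomato_cultivars()
tomato_cultivars <- function() {
  tibble::tibble(
    cultivar    = c("perino", "red datterino", "yellow datterino"),
    glucose     = c(2.62, 3.37, 3.92),
    glucose_sd  = c(0.03, 0.03, 0.02),
    fructose    = c(2.41, 4.02, 4.17),
    fructose_sd = c(0.03, 0.04, 0.11),
    ascorbic    = c(1.0, 1.6, 2.2)
  )
}

#' Default sensor specifications
#'
#' Potential windows match the acquisition protocol: copper-nanoparticle
#' electrodes sweep 0 to +1 V, gold-nanoparticle electrodes -0.5 to +0.6 V and
#' the gold/PEDOT composite -0.5 to +0.5 V.  Points per scan default to
#' 28000/27650/27650 so that window-average subsampling with k = 35 yields
#' 800 + 790 + 790 = 2380 features per concatenated instance.  Peak centres,
#' widths and sensitivities are generator choices producing oxidation peaks of
#' a few tens of microamperes inside each window.
#'
#' @return A tibble with columns `sensor`, `v_min`, `v_max` (V), `points`,
#'   `peak_center`, `peak_width` (V) and `sensitivity` (uA per g/100 g for the
#'   monosaccharide sensors, uA per arbitrary unit for PEDOT).
#' @export
#' @examples
#' default_sensors()
default_sensors <- function() {
  tibble::tibble(
    sensor      = SENSOR_LEVELS,
    v_min       = c(0.0, -0.5, -0.5),
    v_max       = c(1.0, 0.6, 0.5),
    points      = c(28000L, 27650L, 27650L),
    peak_center = c(0.55, 0.25, 0.15),
    peak_width  = c(0.12, 0.10, 0.10),
    sensitivity = c(12, 8, 30)
  )
}

#' Synthetic acquisition configuration
#'
#' Bundles everything the synthetic cyclic-voltammetry generator needs: the
#' cultivar panel, the sensor array, the replicate structure (20 scans per
#' disposable electrode, six electrodes per cultivar/sensor condition) and the
#' nuisance-process parameters (scan-to-scan amplitude decay, additive current
#' noise, electrode-to-electrode variability, capacitive hysteresis).
#'
#' @param cultivars Tibble as returned by [tomato_cultivars()]; must contain
#'   `cultivar`, `glucose`, `fructose` and `ascorbic` columns.
#' @param sensors Tibble as returned by [default_sensors()].
#' @param scans_per_electrode Scans acquired before an electrode is discarded.
#' @param electrodes_per_condition Independent electrodes (sample aliquots)
#'   per cultivar/sensor condition.
#' @param decay_exponent Power-law exponent of the scan-to-scan peak decay;
#'   peak amplitude scales as `(1 + scan_index)^(-decay_exponent)`.  The
#'   default 0.5 is the diffusion-limited value.
#' @param noise_sd Additive Gaussian current noise, uA.
#' @param electrode_sd Relative electrode-to-electrode variability; each
#'   electrode draws a lognormal gain `exp(rnorm(1, 0, electrode_sd))` once.
#' @param baseline_slope Slope of the linear background current, uA/V.
#' @param capacitive Capacitive current offset, uA; added on the forward
#'   branch and subtracted on the backward branch, so every interior potential
#'   shows hysteresis.
#' @param hysteresis_shift Backward-branch peak displacement, V.
#' @param hysteresis_atten Backward-branch peak attenuation factor in (0, 1].
#' @param seed Integer seed; the whole dataset is a deterministic function of
#'   the configuration including this seed.
#'
#' @return A list of class `cv_config`.
#' @export
#' @examples
#' cfg <- generator_config(scans_per_electrode = 2, electrodes_per_condition = 1)
#' cfg$scans_per_electrode
generator_config <- function(cultivars = tomato_cultivars(),
                             sensors = default_sensors(),
                             scans_per_electrode = 20L,
                             electrodes_per_condition = 6L,
                             decay_exponent = 0.5,
                             noise_sd = 0.5,
                             electrode_sd = 0.02,
                             baseline_slope = 5,
                             capacitive = 2,
                             hysteresis_shift = -0.05,
                             hysteresis_atten = 0.5,
                             seed = 1L) {
  cfg <- structure(
    list(
      cultivars = tibble::as_tibble(cultivars),
      sensors = tibble::as_tibble(sensors),
      scans_per_electrode = as.integer(scans_per_electrode),
      electrodes_per_condition = as.integer(electrodes_per_condition),
      decay_exponent = decay_exponent,
      noise_sd = noise_sd,
      electrode_sd = electrode_sd,
      baseline_slope = baseline_slope,
      capacitive = capacitive,
      hysteresis_shift = hysteresis_shift,
      hysteresis_atten = hysteresis_atten,
      seed = as.integer(seed)
    ),
    class = "cv_config"
  )
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  cu <- cfg$cultivars
  se <- cfg$sensors
  need_cu <- c("cultivar", "glucose", "fructose", "ascorbic")
  need_se <- c("sensor", "v_min", "v_max", "points", "peak_center",
               "peak_width", "sensitivity")
  if (!all(need_cu %in% names(cu))) {
    abort(paste0("configuration error: cultivars must have columns ",
                 paste(need_cu, collapse = ", ")))
  }
  if (!all(need_se %in% names(se))) {
    abort(paste0("configuration error: sensors must have columns ",
                 paste(need_se, collapse = ", ")))
  }
  if (!all(se$sensor %in% SENSOR_LEVELS)) {
    abort(paste0("configuration error: unknown sensor name(s) ",
                 paste(setdiff(se$sensor, SENSOR_LEVELS), collapse = ", "),
                 "; allowed: ", paste(SENSOR_LEVELS, collapse = ", ")))
  }
  if (any(se$points < 2)) {
    abort("configuration error: points per scan must be at least 2")
  }
  if (any(se$points %% 2 != 0)) {
    abort("configuration error: points per scan must be even (two branches)")
  }
  if (any(se$v_max <= se$v_min)) {
    abort("configuration error: potential window must have v_max > v_min")
  }
  bad <- se$peak_center <= se$v_min | se$peak_center >= se$v_max
  if (any(bad)) {
    abort(paste0("configuration error: peak center outside potential window for ",
                 paste(se$sensor[bad], collapse = ", ")))
  }
  if (any(c(cu$glucose, cu$fructose, cu$ascorbic) < 0)) {
    abort("configuration error: analyte loadings must be nonnegative")
  }
  if (cfg$scans_per_electrode < 1 || cfg$electrodes_per_condition < 1) {
    abort("configuration error: counts must be at least 1")
  }
  if (cfg$noise_sd < 0 || cfg$electrode_sd < 0) {
    abort("configuration error: noise_sd and electrode_sd must be nonnegative")
  }
  invisible(cfg)
}

#' @export
print.cv_config <- function(x, ...) {
  cat("<cv_config>\n")
  cat("  cultivars:", paste(x$cultivars$cultivar, collapse = ", "), "\n")
  cat("  sensors:  ", paste(x$sensors$sensor, collapse = ", "), "\n")
  cat(sprintf("  %d scans/electrode x %d electrodes/condition, seed %d\n",
              x$scans_per_electrode, x$electrodes_per_condition, x$seed))
  invisible(x)
}

# Analyte loading seen by a sensor: glucose + fructose for the nanoparticle
# sensors, ascorbic acid for PEDOT.
analyte_load <- function(sensor, cultivar_row) {
  if (sensor == "PEDOT") cultivar_row$ascorbic
  else cultivar_row$glucose + cultivar_row$fructose
}
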