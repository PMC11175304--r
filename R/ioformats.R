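#' Flatten a scan dataset to its long tabular form
#'
#' One row per acquired data point, with the eight documented columns:
#' `measurement_id`, `sensor`, `cultivar`, `electrode_id`, `scan_index`,
#' `point_index` (0-based, contiguous within a scan), `potential` (V) and
#' `current` (uA).
#'
#' @param dataset A `cv_dataset` (see [generate_dataset()] / [read_dataset()]).
#' @return A long tibble.
#' @export
as_scan_table <- function(dataset) {
  dataset |>
    dplyr::mutate(point_index = purrr::map(.data$current, ~ seq_along(.x) - 1L)) |>
    tidyr::unnest(c("point_index", "potential", "current")) |>
    dplyr::select("measurement_id", "sensor", "cultivar", "electrode_id",
                  "scan_index", "point_index", "potential", "current")
}

#' Write a scan dataset to disk
#'
#' Writes long-format CSV (either one combined `scans.csv` or one file per
#' sensor) plus a `manifest.json` summarising contents: file list, class-label
#' inventory, per-(cultivar, sensor) scan counts and, for synthetic data, an
#' echo of the generator configuration.  Potentials and currents are stored as
#' plain decimal text with twelve significant digits, so a round trip
#' preserves currents to well within 1e-9 relative.
#'
#' @param dataset A `cv_dataset`.
#' @param path Directory to create/write into.
#' @param split_by_sensor Write one CSV per sensor instead of a combined file.
#' @return The manifest, invisibly (a list, also written as JSON).
#' @export
write_dataset <- function(dataset, path, split_by_sensor = FALSE) {
  if (nrow(dataset) == 0) abort("cannot write an empty dataset")
  lens <- dataset |>
    dplyr::mutate(len = lengths(.data$current)) |>
    dplyr::group_by(.data$measurement_id) |>
    dplyr::summarise(ok = dplyr::n_distinct(.data$len) == 1)
  if (any(!lens$ok)) {
    abort(paste0("validation error: inconsistent scan lengths within measurement(s) ",
                 paste(lens$measurement_id[!lens$ok], collapse = ", ")))
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) abort(paste0("I/O error: cannot create directory ", path))

  long <- as_scan_table(dataset) |>
    dplyr::mutate(potential = signif(.data$potential, 12),
                  current = signif(.data$current, 12))

  files <- if (split_by_sensor) {
    split(long, long$sensor) |>
      purrr::imap_chr(function(df, s) {
        f <- paste0("scans_", s, ".csv")
        readr::write_csv(df, file.path(path, f))
        f
      }) |> unname()
  } else {
    readr::write_csv(long, file.path(path, "scans.csv"))
    "scans.csv"
  }

  counts <- dataset |>
    dplyr::count(.data$cultivar, .data$sensor, name = "n_scans") |>
    dplyr::arrange(.data$cultivar, .data$sensor)

  cfg <- attr(dataset, "config")
  manifest <- list(
    format = "etongue-scan-table-v1",
    files = as.list(files),
    n_scans = nrow(dataset),
    n_measurements = dplyr::n_distinct(dataset$measurement_id),
    classes = sort(unique(dataset$cultivar)),
    counts = counts,
    config = if (!is.null(cfg)) unclass(cfg) else NULL
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE)
  invisible(manifest)
}

#' Read a scan dataset from disk
#'
#' Accepts either a directory written by [write_dataset()] (all CSV files in
#' its manifest are read) or a single long-format CSV file.  The schema is
#' validated: the eight documented columns must be present, sensor names must
#' be known, `point_index` must be 0-based and contiguous within each scan,
#' scan indices contiguous within each measurement, and a measurement must not
#' mix sensors, cultivars or electrodes.
#'
#' @param path Directory or CSV file path.
#' @return A `cv_dataset` tibble with scans ordered by measurement and scan
#'   index.
#' @export
read_dataset <- function(path) {
  files <- if (dir.exists(path)) {
    mf <- file.path(path, "manifest.json")
    if (file.exists(mf)) {
      file.path(path, unlist(jsonlite::read_json(mf)$files))
    } else {
      list.files(path, pattern = "\\.csv$", full.names = TRUE)
    }
  } else {
    if (!file.exists(path)) abort(paste0("I/O error: no such file ", path))
    path
  }
  if (length(files) == 0) abort(paste0("I/O error: no CSV files under ", path))

  cols <- readr::cols(
    measurement_id = readr::col_character(),
    sensor = readr::col_character(),
    cultivar = readr::col_character(),
    electrode_id = readr::col_character(),
    scan_index = readr::col_integer(),
    point_index = readr::col_integer(),
    potential = readr::col_double(),
    current = readr::col_double()
  )
  long <- purrr::map(files, function(f) {
    df <- readr::read_csv(f, col_types = cols)
    missing <- setdiff(names(cols$cols), names(df))
    if (length(missing) > 0) {
      abort(paste0("schema error in ", f, ": missing column(s) ",
                   paste(missing, collapse = ", ")))
    }
    df
  }) |> purrr::list_rbind()

  bad_sensor <- setdiff(unique(long$sensor), SENSOR_LEVELS)
  if (length(bad_sensor) > 0) {
    abort(paste0("schema error: unknown sensor name(s) ",
                 paste(bad_sensor, collapse = ", "),
                 "; allowed names: ", paste(SENSOR_LEVELS, collapse = ", ")))
  }

  mixed <- long |>
    dplyr::group_by(.data$measurement_id) |>
    dplyr::summarise(ok = dplyr::n_distinct(.data$sensor) == 1 &&
                       dplyr::n_distinct(.data$cultivar) == 1 &&
                       dplyr::n_distinct(.data$electrode_id) == 1)
  if (any(!mixed$ok)) {
    abort(paste0("schema error: mixed sensor/cultivar/electrode inside measurement(s) ",
                 paste(mixed$measurement_id[!mixed$ok], collapse = ", ")))
  }

  nested <- long |>
    dplyr::arrange(.data$measurement_id, .data$scan_index, .data$point_index) |>
    dplyr::group_by(.data$measurement_id, .data$sensor, .data$cultivar,
                    .data$electrode_id, .data$scan_index) |>
    dplyr::summarise(
      contiguous = identical(.data$point_index, seq_len(dplyr::n()) - 1L),
      potential = list(.data$potential),
      current = list(.data$current),
      .groups = "drop"
    )
  if (any(!nested$contiguous)) {
    off <- nested[!nested$contiguous, ]
    abort(paste0("schema error: non-contiguous point_index in measurement ",
                 off$measurement_id[1], ", scan ", off$scan_index[1]))
  }
  gaps <- nested |>
    dplyr::group_by(.data$measurement_id) |>
    dplyr::summarise(ok = identical(sort(.data$scan_index), seq_len(dplyr::n()) - 1L))
  if (any(!gaps$ok)) {
    abort(paste0("schema error: scan_index not contiguous from 0 in measurement(s) ",
                 paste(gaps$measurement_id[!gaps$ok], collapse = ", ")))
  }

  out <- nested |> dplyr::select(-"contiguous")
  structure(out, class = c("cv_dataset", class(out)))
}
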