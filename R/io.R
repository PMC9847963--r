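#' Read and write annotation and measurement tables
#'
#' Plain-CSV interchange for the three table schemas the pipeline uses:
#' detector bounding boxes (`boxes.csv`), manual fiducials
#' (`fiducials.csv`) and joint measurements (`measurements.csv`). Columns
#' are type-checked on read; the upstream image format for the raster data
#' these annotations were derived from is NIfTI-1, but raster images are
#' never consumed here.
#'
#' @param path File path.
#' @return A tibble in the corresponding schema.
#' @name annotation_io
NULL

read_checked_csv <- function(path, col_types, schema, what) {
  if (!file.exists(path)) {
    abort_validation(sprintf("File not found: %s", path))
  }
  # parse problems surface as a classed error below, not as readr warnings
  df <- suppressWarnings(
    readr::read_csv(path, col_types = col_types, progress = FALSE))
  prob <- readr::problems(df)
  if (nrow(prob)) {
    abort_validation(sprintf("Malformed %s: parsing problem at row %d (%s).",
                             what, prob$row[1], prob$expected[1]))
  }
  check_schema(df, schema, what)
  df
}

#' @rdname annotation_io
#' @export
read_boxes <- function(path) {
  read_checked_csv(path, readr::cols(participant_id = readr::col_character(),
                                     side = readr::col_character(),
                                     .default = readr::col_double()),
                   box_table_schema, "boxes table")
}

#' @rdname annotation_io
#' @export
read_fiducials <- function(path) {
  read_checked_csv(path, readr::cols(participant_id = readr::col_character(),
                                     side = readr::col_character(),
                                     .default = readr::col_double()),
                   fiducial_table_schema, "fiducials table")
}

#' @rdname annotation_io
#' @export
read_measurements <- function(path) {
  read_checked_csv(path,
                   readr::cols(participant_id = readr::col_character(),
                               s_excluded = readr::col_logical(),
                               .default = readr::col_double()),
                   c("participant_id", "timepoint_ms", "iad_m_mm", "iad_a_mm",
                     "iad_s_mm", "s_excluded"),
                   "measurements table")
}

#' @rdname annotation_io
#' @param measurements Tibble from [pair_timepoints()].
#' @export
write_measurements <- function(measurements, path) {
  readr::write_csv(measurements, path, na = "")
  invisible(path)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `boxes.csv`, `fiducials.csv`, `truth.csv` and the resolved
#' `config.json` (including the seed and a config hash for provenance).
#' Identical datasets produce byte-identical files.
#'
#' @param dataset An `iad_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "iad_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(dataset$boxes, file.path(dir, "boxes.csv"))
  readr::write_csv(dataset$fiducials, file.path(dir, "fiducials.csv"))
  readr::write_csv(dataset$truth, file.path(dir, "truth.csv"))
  cfg <- unclass(dataset$config)
  cfg$config_hash <- rlang::hash(unclass(dataset$config))
  cfg$geometry <- unclass(dataset$geometry)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
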