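#' Read and write the package's CSV dialects
#'
#' Count datasets are CSV with header `cell_id,strain,condition_uM,count`
#' (one row per cell, UTF-8); spot tables are CSV with header
#' `spot_id,cell_id,intensity,peak_height`, with control intensities in a
#' separate single-column CSV with header `intensity`. Readers validate the
#' header and value domains and fail with the offending file named.
#'
#' @param path File path.
#' @return `read_counts()` returns a validated count dataset tibble;
#'   `read_spots()` returns a [spot_table].
#' @name burstfish_io
NULL

read_csv_strict <- function(path, expected_header) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path),
      class = "burstfish_io_error"
    )
  }
  header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  if (!identical(header, expected_header)) {
    abort(
      sprintf(
        "%s: expected header `%s`, found `%s`.",
        path, paste(expected_header, collapse = ","),
        paste(header, collapse = ",")
      ),
      class = "burstfish_format_error"
    )
  }
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname burstfish_io
#' @export
read_counts <- function(path) {
  df <- read_csv_strict(path, c("cell_id", "strain", "condition_uM", "count"))
  if (nrow(df) == 0L) {
    abort(sprintf("%s: empty count dataset.", path),
      class = "burstfish_format_error"
    )
  }
  if (!is.numeric(df$count) || any(df$count != floor(df$count))) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$count))) |
      df$count != floor(df$count))[1L]
    abort(
      sprintf("%s: non-integer count at data row %d.", path, bad),
      class = "burstfish_format_error"
    )
  }
  validate_count_dataset(df)
}

#' @rdname burstfish_io
#' @param counts A count dataset tibble.
#' @export
write_counts <- function(counts, path) {
  counts <- validate_count_dataset(counts)
  readr::write_csv(counts, path, progress = FALSE)
  invisible(path)
}

#' @rdname burstfish_io
#' @param control_path Path of the single-column control-intensity CSV.
#' @export
read_spots <- function(path, control_path = NULL) {
  df <- read_csv_strict(path, c("spot_id", "cell_id", "intensity",
    "peak_height"))
  control <- numeric()
  if (!is.null(control_path)) {
    cdf <- read_csv_strict(control_path, "intensity")
    control <- as.numeric(cdf$intensity)
  }
  spot_table(df, control_intensities = control)
}

#' @rdname burstfish_io
#' @param spots A [spot_table].
#' @export
write_spots <- function(spots, path, control_path = NULL) {
  if (!inherits(spots, "spot_table")) {
    abort("`spots` must be a spot_table.", class = "burstfish_param_error")
  }
  readr::write_csv(spots$spots, path, progress = FALSE)
  if (!is.null(control_path)) {
    readr::write_csv(tibble(intensity = spots$control_intensities),
      control_path,
      progress = FALSE
    )
  }
  invisible(path)
}

#' Write an intensity calibration as JSON
#'
#' Serializes the threshold, unit intensity and mixture components as
#' `{fp_threshold, unit_intensity, components: [{weight, mean, sd}, ...]}`.
#'
#' @param calib An [intensity_calibration()].
#' @param path Output path.
#' @export
write_calibration <- function(calib, path) {
  obj <- list(
    fp_threshold = calib$fp_threshold,
    unit_intensity = calib$unit_intensity,
    components = purrr::pmap(
      calib$mixture,
      function(weight, mean, sd) list(weight = weight, mean = mean, sd = sd)
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(path)
}
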