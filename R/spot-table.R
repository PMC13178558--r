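#' Spot table: per-spot intensities plus a negative-control population
#'
#' Container mirroring the output of single-molecule FISH spot detection:
#' one row per diffraction-limited spot (`spot_id`, `cell_id`, integrated
#' `intensity`, `peak_height`) together with the integrated intensities of
#' spots detected in a no-target negative-control sample (used downstream to
#' set the false-positive threshold). Cells listed in `cells` but absent from
#' `spots` are silent (zero detected spots).
#'
#' @param spots Tibble with columns `spot_id`, `cell_id`, `intensity`,
#'   `peak_height`.
#' @param control_intensities Numeric vector of control-spot intensities.
#' @param cells Character vector of all cell ids covered by the experiment
#'   (defaults to the cells present in `spots`).
#' @return An object of class `spot_table`.
#' @export
spot_table <- function(spots, control_intensities = numeric(),
                       cells = unique(spots$cell_id)) {
  required <- c("spot_id", "cell_id", "intensity", "peak_height")
  missing_cols <- setdiff(required, names(spots))
  if (length(missing_cols) > 0L) {
    abort(
      paste0("spot table is missing column(s): ",
        paste(missing_cols, collapse = ", ")),
      class = "burstfish_format_error"
    )
  }
  if (any(spots$intensity < 0) || any(spots$peak_height < 0)) {
    abort("spot intensities must be non-negative.",
      class = "burstfish_format_error"
    )
  }
  if (any(is.na(control_intensities)) || any(control_intensities < 0)) {
    abort("control intensities must be non-negative.",
      class = "burstfish_format_error"
    )
  }
  if (!all(spots$cell_id %in% cells)) {
    abort("every spot must reference a cell listed in `cells`.",
      class = "burstfish_format_error"
    )
  }
  structure(
    list(
      spots = as_tibble(spots),
      control_intensities = as.numeric(control_intensities),
      cells = as.character(cells)
    ),
    class = "spot_table"
  )
}

#' @export
print.spot_table <- function(x, ...) {
  cat(sprintf(
    "<spot_table>  %d spots in %d cells;  %d control spots\n",
    nrow(x$spots), length(x$cells), length(x$control_intensities)
  ))
  invisible(x)
}

#' Generate a synthetic smFISH spot table from true counts
#'
#' Emulates the intensity structure of single-molecule FISH data: a cell
#' carrying `k` mRNA molecules emits `k` diffraction-limited spots whose
#' integrated intensities are Gaussian around the single-molecule unit
#' intensity (relative spread `intensity_cv`), so the cell's total intensity
#' is centred on `k * unit_intensity`. A negative-control population of
#' `n_control` background spots is drawn from a half-normal with scale
#' `control_scale`, well below genuine single-molecule intensities when
#' `control_scale` is a small fraction of `unit_intensity`. Peak heights are
#' carried as metadata (intensity scaled down with independent jitter).
#'
#' @param counts Count dataset (tibble with `cell_id`, `strain`,
#'   `condition_uM`, `count`) giving the true copy number per cell.
#' @param unit_intensity Mean integrated intensity of one molecule (a.u., > 0).
#' @param intensity_cv Per-spot coefficient of variation, in (0, 0.5).
#' @param n_control Number of negative-control spots to draw (>= 0).
#' @param control_scale Half-normal scale of control intensities (a.u., >= 0);
#'   default 15% of `unit_intensity`.
#' @param seed Optional integer seed.
#' @return A [spot_table] whose `cells` cover every cell in `counts`
#'   (silent cells emit no spots).
#' @examples
#' cts <- sample_zinb(zinb_params(0.3, 2, 0.5), 20, seed = 1)
#' generate_spot_table(cts, unit_intensity = 100, seed = 1)
#' @export
generate_spot_table <- function(counts, unit_intensity = 100,
                                intensity_cv = 0.05, n_control = 500,
                                control_scale = 0.15 * unit_intensity,
                                seed = NULL) {
  counts <- validate_count_dataset(counts)
  check_scalar_num(unit_intensity, "unit_intensity")
  check_scalar_num(intensity_cv, "intensity_cv")
  check_scalar_num(control_scale, "control_scale")
  if (unit_intensity <= 0 || control_scale < 0) {
    abort("`unit_intensity` must be > 0 and `control_scale` >= 0.",
      class = "burstfish_param_error"
    )
  }
  if (intensity_cv <= 0 || intensity_cv >= 0.5) {
    abort("`intensity_cv` must lie in (0, 0.5).",
      class = "burstfish_param_error"
    )
  }
  if (!is.null(seed)) set.seed(seed)

  n_spots <- sum(counts$count)
  cell_of_spot <- rep(counts$cell_id, counts$count)
  sd_spot <- intensity_cv * unit_intensity
  intensity <- rnorm(n_spots, mean = unit_intensity, sd = sd_spot)
  intensity <- pmax(intensity, 0)
  peak_height <- intensity * 0.4 * exp(rnorm(n_spots, 0, 0.1))
  spots <- tibble(
    spot_id = sprintf("spot_%06d", seq_len(n_spots)),
    cell_id = cell_of_spot,
    intensity = intensity,
    peak_height = peak_height
  )
  control <- abs(rnorm(as.integer(n_control), 0, 1)) * control_scale
  spot_table(spots, control_intensities = control, cells = counts$cell_id)
}
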