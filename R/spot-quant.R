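#' False-positive intensity threshold from a negative control
#'
#' The 99.9th percentile of spot intensities observed in a no-target control
#' (e.g. a deletion strain lacking the probed transcript). Spots at or below
#' this intensity are treated as nonspecific background. The percentile uses
#' the linear-interpolation convention (sorted 0-based position `(n-1) * q`,
#' `stats::quantile` type 7) so the value is bit-reproducible.
#'
#' @param control_intensities Non-empty numeric vector of control-spot
#'   intensities (a.u.).
#' @param prob Percentile level; default 0.999.
#' @return The threshold intensity (a.u.).
#' @examples
#' fp_threshold(1:1000) # 999.001
#' @export
fp_threshold <- function(control_intensities, prob = 0.999) {
  if (length(control_intensities) == 0L) {
    abort("control intensity list is empty.",
      class = "burstfish_domain_error"
    )
  }
  if (any(is.na(control_intensities))) {
    abort("control intensities contain NA.", class = "burstfish_domain_error")
  }
  quantile(control_intensities, probs = prob, type = 7, names = FALSE)
}

#' Fit a multi-Gaussian model to spot intensities
#'
#' Maximum-likelihood Gaussian mixture (EM, unequal variances) fitted to the
#' integrated intensities of spots from a low-expressing calibration strain.
#' Quantal intensities put the components near integer multiples of the
#' single-molecule intensity; the mean of the lowest-mean component is the
#' unit intensity of one mRNA molecule. Components are returned in ascending
#' order of mean. The fit is deterministic (model-based hierarchical
#' initialization).
#'
#' @param intensities Numeric vector of spot intensities; at least
#'   `10 * n_components` values.
#' @param n_components Number of Gaussian components (>= 1); default 3.
#' @return A tibble with one row per component: `weight`, `mean`, `sd`,
#'   sorted by ascending `mean`.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(500, 100, 8), rnorm(500, 200, 8))
#' fit_intensity_mixture(x, n_components = 2)
#' @export
fit_intensity_mixture <- function(intensities, n_components = 3) {
  if (!is.numeric(n_components) || length(n_components) != 1L ||
    n_components < 1 || n_components != floor(n_components)) {
    abort("`n_components` must be a single integer >= 1.",
      class = "burstfish_param_error"
    )
  }
  n_components <- as.integer(n_components)
  if (length(intensities) < 10L * n_components) {
    abort(
      sprintf(
        "need at least %d intensities to fit %d components (got %d).",
        10L * n_components, n_components, length(intensities)
      ),
      class = "burstfish_fit_error"
    )
  }
  fit <- mclust::Mclust(as.numeric(intensities),
    G = n_components,
    modelNames = "V", verbose = FALSE
  )
  if (is.null(fit)) {
    abort(
      sprintf("EM failed to fit a %d-component mixture.", n_components),
      class = "burstfish_fit_error"
    )
  }
  mixture <- tibble(
    weight = as.numeric(fit$parameters$pro),
    mean = as.numeric(fit$parameters$mean),
    sd = sqrt(as.numeric(fit$parameters$variance$sigmasq))
  )
  if (nrow(mixture) == n_components && length(mixture$sd) == 1L &&
    n_components > 1L) {
    mixture$sd <- rep(mixture$sd, n_components)
  }
  arrange(mixture, .data$mean)
}

#' Intensity calibration: threshold, unit intensity, mixture
#'
#' Bundles the two calibration quantities the quantification rule needs —
#' the false-positive threshold from the negative control and the
#' single-molecule unit intensity (mean of the first Gaussian component) —
#' together with the full fitted mixture.
#'
#' @param fp_threshold False-positive intensity threshold (a.u., >= 0).
#' @param mixture Tibble of mixture components (`weight`, `mean`, `sd`),
#'   ascending in `mean`; weights must sum to 1.
#' @return An object of class `intensity_calibration` with fields
#'   `fp_threshold`, `unit_intensity`, `mixture`.
#' @export
intensity_calibration <- function(fp_threshold, mixture) {
  check_scalar_num(fp_threshold, "fp_threshold")
  if (fp_threshold < 0) {
    abort("`fp_threshold` must be >= 0.", class = "burstfish_param_error")
  }
  required <- c("weight", "mean", "sd")
  if (!all(required %in% names(mixture)) || nrow(mixture) < 1L) {
    abort("`mixture` must have columns weight, mean, sd and >= 1 row.",
      class = "burstfish_param_error"
    )
  }
  if (abs(sum(mixture$weight) - 1) > 1e-9) {
    abort("mixture weights must sum to 1.", class = "burstfish_param_error")
  }
  mixture <- arrange(as_tibble(mixture), .data$mean)
  unit <- mixture$mean[[1L]]
  if (unit <= 0) {
    abort("unit intensity (first-component mean) must be > 0.",
      class = "burstfish_param_error"
    )
  }
  structure(
    list(
      fp_threshold = as.numeric(fp_threshold),
      unit_intensity = unit,
      mixture = mixture
    ),
    class = "intensity_calibration"
  )
}

#' @export
print.intensity_calibration <- function(x, ...) {
  cat(sprintf(
    "<intensity_calibration>  fp_threshold = %.4g  unit_intensity = %.4g  (%d components)\n",
    x$fp_threshold, x$unit_intensity, nrow(x$mixture)
  ))
  invisible(x)
}

#' Calibrate intensities from a spot table
#'
#' Convenience wrapper: derives the false-positive threshold from the
#' table's negative-control intensities and the unit intensity from a
#' multi-Gaussian fit to the above-threshold spot intensities.
#'
#' @param spots A [spot_table].
#' @param n_components Gaussian components for the mixture fit; default 3.
#' @param prob Control percentile for the threshold; default 0.999.
#' @return An [intensity_calibration()] object.
#' @export
calibrate_intensities <- function(spots, n_components = 3, prob = 0.999) {
  if (!inherits(spots, "spot_table")) {
    abort("`spots` must be a spot_table.", class = "burstfish_param_error")
  }
  thr <- fp_threshold(spots$control_intensities, prob = prob)
  keep <- spots$spots$intensity > thr
  mixture <- fit_intensity_mixture(spots$spots$intensity[keep],
    n_components = n_components
  )
  intensity_calibration(thr, mixture)
}

#' Per-cell mRNA counts from spot intensities
#'
#' Applies the quantification rule: spots with intensity at or below the
#' false-positive threshold are discarded; for each cell the surviving
#' integrated intensities are summed and divided by the single-molecule unit
#' intensity, and the ratio is rounded to the nearest integer (floored at 0).
#' Cells present in the table but with no surviving spot get count 0.
#'
#' @param spots A [spot_table].
#' @param calib An [intensity_calibration()] (or anything with numeric fields
#'   `fp_threshold` and `unit_intensity`).
#' @param strain,condition_uM Labels attached to the resulting cells.
#' @return A count dataset tibble (`cell_id`, `strain`, `condition_uM`,
#'   `count`), one row per cell in `spots$cells`, in that order.
#' @examples
#' cts <- sample_zinb(zinb_params(0.3, 2, 0.5), 50, seed = 1)
#' tab <- generate_spot_table(cts, seed = 2)
#' calib <- calibrate_intensities(tab, n_components = 2)
#' quantify_counts(tab, calib)
#' @export
quantify_counts <- function(spots, calib, strain = "quantified",
                            condition_uM = 0) {
  if (!inherits(spots, "spot_table")) {
    abort("`spots` must be a spot_table.", class = "burstfish_param_error")
  }
  if (is.null(calib$unit_intensity) || calib$unit_intensity <= 0) {
    abort("`calib$unit_intensity` must be > 0.",
      class = "burstfish_param_error"
    )
  }
  thr <- calib$fp_threshold %||% 0
  surviving <- filter(spots$spots, .data$intensity > thr)
  totals <- surviving %>%
    group_by(.data$cell_id) %>%
    summarise(total = sum(.data$intensity), .groups = "drop")
  total <- setNames(rep(0, length(spots$cells)), spots$cells)
  total[totals$cell_id] <- totals$total
  counts <- pmax(0L, as.integer(round(total / calib$unit_intensity)))
  new_count_dataset(
    cell_id = spots$cells, strain = strain,
    condition_uM = condition_uM, count = counts
  )
}
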