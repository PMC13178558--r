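#' Plot per-condition mRNA count distributions
#'
#' Relative-frequency histograms of per-cell copy number, faceted by strain
#' and tryptophan condition — the standard view of smFISH population data.
#'
#' @param counts Count dataset tibble.
#' @param max_count Right edge of the x axis (counts above are pooled into
#'   the last bin); default the observed maximum.
#' @return A ggplot object.
#' @export
plot_count_distribution <- function(counts, max_count = NULL) {
  counts <- validate_count_dataset(counts)
  if (!is.null(max_count)) {
    counts$count <- pmin(counts$count, as.integer(max_count))
  }
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_bar(
      ggplot2::aes(y = ggplot2::after_stat(.data$prop)),
      fill = "grey30", width = 0.9
    ) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$strain),
      cols = ggplot2::vars(.data$condition_uM),
      labeller = ggplot2::label_both
    ) +
    ggplot2::labs(x = "mRNA copies per cell", y = "relative frequency") +
    ggplot2::theme_bw()
}

#' Noise and burstiness versus mean expression
#'
#' CV^2 and Fano factor per group plotted against the group mean, with the
#' Fano = 1 Poisson reference line that separates bursty from non-bursty
#' expression.
#'
#' @param noise_summary Output of [summarize_counts()].
#' @return A ggplot object.
#' @export
plot_noise_vs_mean <- function(noise_summary) {
  long <- tidyr::pivot_longer(noise_summary, c("cv2", "fano"),
    names_to = "statistic", values_to = "value"
  )
  ref <- tibble(statistic = "fano", yintercept = 1)
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$mu, y = .data$value, colour = .data$strain
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(
      data = ref, ggplot2::aes(yintercept = .data$yintercept),
      linetype = "dashed", colour = "grey50"
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$statistic), scales = "free_y") +
    ggplot2::labs(x = "mean mRNA per cell", y = NULL) +
    ggplot2::theme_bw()
}

#' @describeIn run_mcmc Marginal posterior histograms and trace of the
#'   retained draws.
#' @param object A `posterior_chain`.
#' @param ... Unused.
#' @export
autoplot.posterior_chain <- function(object, ...) {
  long <- tidyr::pivot_longer(
    mutate(object$samples, draw = dplyr::row_number()),
    c("omega", "r", "p"),
    names_to = "parameter", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter), scales = "free") +
    ggplot2::labs(
      x = NULL, y = "retained draws",
      title = sprintf("ZINB posterior (acceptance %.2f)",
        object$acceptance_rate)
    ) +
    ggplot2::theme_bw()
}

#' @describeIn fit_exp_decay Data and fitted one-phase decay curve.
#' @param object An `exp_decay_fit`.
#' @export
autoplot.exp_decay_fit <- function(object, ...) {
  grid <- tibble(
    x = seq(min(object$data$x), max(object$data$x), length.out = 200)
  )
  grid$y <- predict(object, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(
      title = sprintf("one-phase decay fit, R^2 = %.3f", object$r_squared)
    ) +
    ggplot2::theme_bw()
}
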