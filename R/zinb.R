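#' Zero-inflated negative binomial parameters
#'
#' Bundle of the three parameters of the zero-inflated negative binomial
#' (ZINB) model of per-cell mRNA copy number: with probability `omega` a cell
#' is transcriptionally repressed and contributes a structural zero; otherwise
#' its count follows a negative binomial with shape `r` and per-molecule
#' success probability `p`, pmf
#' \deqn{P(k) = \binom{k+r-1}{k} p^k (1-p)^r.}
#' Under this parameterization the mean is \eqn{(1-\omega)\, r p/(1-p)},
#' the burst size is \eqn{b = p/(1-p)} and the burst frequency is proxied by
#' \eqn{f = r} (bursts per mRNA lifetime).
#'
#' @param omega Repression (zero-inflation) probability in \[0, 1\].
#' @param r Negative-binomial shape (burst-frequency proxy), > 0.
#' @param p Negative-binomial success probability in (0, 1).
#'
#' @return An object of class `zinb_params`: a named list with elements
#'   `omega`, `r`, `p`.
#' @examples
#' zinb_params(omega = 0.5, r = 2, p = 0.7)
#' @export
zinb_params <- function(omega, r, p) {
  check_scalar_num(omega, "omega")
  check_scalar_num(r, "r")
  check_scalar_num(p, "p")
  if (omega < 0 || omega > 1) {
    abort("`omega` must lie in [0, 1].", class = "burstfish_param_error")
  }
  if (r <= 0) {
    abort("`r` must be > 0.", class = "burstfish_param_error")
  }
  if (p <= 0 || p >= 1) {
    abort("`p` must lie strictly in (0, 1).", class = "burstfish_param_error")
  }
  structure(list(omega = omega, r = r, p = p), class = "zinb_params")
}

#' @export
print.zinb_params <- function(x, ...) {
  cat(sprintf(
    "<zinb_params>  omega = %.4g  r = %.4g  p = %.4g  (mean = %.4g)\n",
    x$omega, x$r, x$p, zinb_mean(x)
  ))
  invisible(x)
}

#' @describeIn zinb_params Vector view `c(omega, r, p)` of the parameters.
#' @param x A `zinb_params` object.
#' @param ... Unused.
#' @export
as.double.zinb_params <- function(x, ...) {
  c(omega = x$omega, r = x$r, p = x$p)
}

#' Build `zinb_params` from a length-3 vector `[omega, r, p]`.
#'
#' @param theta Numeric vector `c(omega, r, p)`.
#' @return A [zinb_params] object.
#' @export
as_zinb_params <- function(theta) {
  if (inherits(theta, "zinb_params")) {
    return(theta)
  }
  if (!is.numeric(theta) || length(theta) != 3L) {
    abort("`theta` must be a numeric vector [omega, r, p].",
      class = "burstfish_param_error"
    )
  }
  zinb_params(theta[[1L]], theta[[2L]], theta[[3L]])
}

zinb_mean <- function(params) {
  (1 - params$omega) * params$r * params$p / (1 - params$p)
}

zinb_var <- function(params) {
  m <- params$r * params$p / (1 - params$p)
  b <- params$p / (1 - params$p)
  (1 - params$omega) * m * (1 + b + params$omega * m)
}

#' ZINB probability mass function
#'
#' Probability of observing `x` mRNA copies in a cell under the zero-inflated
#' negative binomial model:
#' \eqn{P(0) = \omega + (1-\omega)(1-p)^r} and, for \eqn{k > 0},
#' \eqn{P(k) = (1-\omega)\binom{k+r-1}{k}p^k(1-p)^r}. Evaluated in log space
#' through the log-gamma function so large counts and extreme parameters do
#' not underflow.
#'
#' @param x Vector of non-negative integer counts.
#' @param params A [zinb_params] object (or `[omega, r, p]` vector).
#' @param log If `TRUE`, return log-probabilities.
#'
#' @return Numeric vector of (log-)probabilities, one per element of `x`.
#' @examples
#' dzinb(0:5, zinb_params(0.5, 2, 0.7))
#' @export
dzinb <- function(x, params, log = FALSE) {
  params <- as_zinb_params(params)
  if (any(x < 0) || any(x != floor(x))) {
    abort("`x` must contain non-negative integers.",
      class = "burstfish_domain_error"
    )
  }
  lp <- zinb_logpmf_cpp(as.numeric(x), params$omega, params$r, params$p)
  if (log) lp else exp(lp)
}

#' Draw per-cell mRNA counts from the ZINB model
#'
#' Each cell is silenced (count 0) with probability `omega`; otherwise its
#' count is drawn from NB(`r`, `p`) under the pmf documented in [dzinb()].
#'
#' @param params A [zinb_params] object.
#' @param n_cells Number of cells to draw (>= 0).
#' @param strain Strain label attached to every cell.
#' @param condition_uM Tryptophan concentration in micromolar attached to
#'   every cell.
#' @param seed Optional integer seed; if supplied the draw is reproducible.
#'
#' @return A count dataset: tibble with columns `cell_id`, `strain`,
#'   `condition_uM`, `count`.
#' @examples
#' sample_zinb(zinb_params(0.5, 2, 0.7), n_cells = 10, seed = 1)
#' @export
sample_zinb <- function(params, n_cells, strain = "synthetic",
                        condition_uM = 0, seed = NULL) {
  params <- as_zinb_params(params)
  if (!is.numeric(n_cells) || length(n_cells) != 1L || n_cells < 0 ||
    n_cells != floor(n_cells)) {
    abort("`n_cells` must be a single non-negative integer.",
      class = "burstfish_param_error"
    )
  }
  if (!is.null(seed)) set.seed(seed)
  n_cells <- as.integer(n_cells)
  if (n_cells == 0L) {
    return(new_count_dataset(character(), strain, condition_uM, integer()))
  }
  silenced <- runif(n_cells) < params$omega
  counts <- integer(n_cells)
  n_active <- sum(!silenced)
  if (n_active > 0L) {
    # R's dnbinom prob is P(failure before success) complement: NB(size, prob)
    # with prob = 1 - p matches P(k) = C(k+r-1,k) p^k (1-p)^r.
    counts[!silenced] <- rnbinom(n_active, size = params$r, prob = 1 - params$p)
  }
  new_count_dataset(
    cell_id = sprintf("cell_%05d", seq_len(n_cells)),
    strain = strain, condition_uM = condition_uM, count = counts
  )
}

new_count_dataset <- function(cell_id, strain, condition_uM, count) {
  tibble(
    cell_id = as.character(cell_id),
    strain = as.character(strain),
    condition_uM = as.double(condition_uM),
    count = as.integer(count)
  )
}

#' Validate a count dataset
#'
#' Checks the per-cell count table contract: columns `cell_id`, `strain`,
#' `condition_uM`, `count`; integer counts >= 0; unique
#' (strain, condition_uM, cell_id).
#'
#' @param counts A data frame of per-cell counts.
#' @return The validated tibble, invisibly coerced column types.
#' @export
validate_count_dataset <- function(counts) {
  required <- c("cell_id", "strain", "condition_uM", "count")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols) > 0L) {
    abort(
      paste0(
        "count dataset is missing column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "burstfish_format_error"
    )
  }
  if (any(is.na(counts$count)) || any(counts$count < 0) ||
    any(counts$count != floor(counts$count))) {
    abort("`count` must contain non-negative integers.",
      class = "burstfish_format_error"
    )
  }
  key <- paste(counts$strain, counts$condition_uM, counts$cell_id, sep = "\r")
  if (anyDuplicated(key) > 0L) {
    abort("(strain, condition_uM, cell_id) must be unique.",
      class = "burstfish_format_error"
    )
  }
  new_count_dataset(counts$cell_id, counts$strain, counts$condition_uM,
    counts$count)
}

check_scalar_num <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
      class = "burstfish_param_error"
    )
  }
  invisible(x)
}
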