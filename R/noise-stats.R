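#' Population noise and burstiness summaries per group
#'
#' Per (strain, condition) group of a count dataset, computes the summary
#' statistics used to characterize transcriptional heterogeneity:
#' mean `mu`, sample standard deviation `sigma` (n-1 denominator), noise
#' `cv2 = sigma^2 / mu^2`, burstiness `fano = sigma^2 / mu` (Fano factor;
#' 1 for Poisson, > 1 indicates bursty expression), and the fractions of
#' transcriptionally silent (count 0) and on (count >= 1) cells. Groups with
#' `mu = 0` get `cv2` and `fano` flagged `NA` (undefined), never 0/0.
#'
#' @param counts Count dataset tibble (`cell_id`, `strain`, `condition_uM`,
#'   `count`).
#' @param ... Optional tidy-select grouping columns; defaults to
#'   `strain, condition_uM`.
#' @return Tibble with one row per group: grouping columns plus `n_cells`,
#'   `mu`, `sigma`, `cv2`, `fano`, `frac_silent`, `frac_on`.
#' @examples
#' cts <- sample_zinb(zinb_params(0.3, 2, 0.5), 200, seed = 1)
#' summarize_counts(cts)
#' @export
summarize_counts <- function(counts, ...) {
  counts <- validate_count_dataset(counts)
  if (nrow(counts) == 0L) {
    abort("count dataset is empty.", class = "burstfish_domain_error")
  }
  groups <- rlang::enquos(...)
  if (length(groups) == 0L) {
    grouped <- group_by(counts, .data$strain, .data$condition_uM)
  } else {
    grouped <- group_by(counts, !!!groups)
  }
  out <- summarise(grouped,
    n_cells = dplyr::n(),
    mu = mean(.data$count),
    sigma = if (dplyr::n() > 1L) sd(.data$count) else 0,
    frac_silent = mean(.data$count == 0L),
    frac_on = mean(.data$count >= 1L),
    .groups = "drop"
  )
  out %>%
    mutate(
      cv2 = ifelse(.data$mu > 0, .data$sigma^2 / .data$mu^2, NA_real_),
      fano = ifelse(.data$mu > 0, .data$sigma^2 / .data$mu, NA_real_)
    ) %>%
    select(
      dplyr::all_of(setdiff(names(out), c("frac_silent", "frac_on"))),
      "cv2", "fano", "frac_silent", "frac_on"
    ) %>%
    arrange(dplyr::across(dplyr::all_of(
      intersect(c("strain", "condition_uM"), names(out))
    )))
}

#' Spearman rank correlation with exact small-sample permutation p-value
#'
#' Spearman's rho between paired observations, with a two-sided p-value
#' computed by full enumeration of all `n!` rank permutations when
#' `n <= exact_max` (default 8): `p = #\{|rho_perm| >= |rho_obs|\} / n!`,
#' the standard exact-test convention (>= in the tail count). For larger
#' samples a t-distribution approximation
#' (`t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` df) is used and a notice is
#' emitted. For n = 4 perfectly monotone data the exact two-sided p-value is
#' 2/24 = 0.0833 (prints as 0.08).
#'
#' @param data Optional data frame; if supplied, `x` and `y` are evaluated
#'   inside it, so the function pipes: `df |> spearman_exact(mu, cv2)`.
#' @param x,y Paired numeric vectors (or column names when `data` is given)
#'   of equal length n >= 3.
#' @param exact_max Largest n for which full enumeration is used; default 8.
#' @return One-row tibble: `rho`, `p_two_sided`, `n`, `method`
#'   (`"exact permutation"` or `"t approximation"`).
#' @examples
#' spearman_exact(x = 1:4, y = c(9, 7, 5, 2)) # rho = -1, p = 2/24
#' @export
spearman_exact <- function(data = NULL, x, y, exact_max = 8L) {
  if (!is.null(data)) {
    x <- rlang::eval_tidy(rlang::enquo(x), data)
    y <- rlang::eval_tidy(rlang::enquo(y), data)
  }
  n <- length(x)
  if (length(y) != n) {
    abort("`x` and `y` must have equal length.",
      class = "burstfish_domain_error"
    )
  }
  if (n < 3L) {
    abort("need at least 3 paired observations.",
      class = "burstfish_domain_error"
    )
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("`x` and `y` must be finite.", class = "burstfish_domain_error")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- spearman_rho(rx, ry)
  if (n <= exact_max) {
    perms <- permute_indices(n)
    # rho for every permutation of the y ranks against the fixed x ranks;
    # sum((ry_perm - mean)(rx - mean)) = ry_perm . (rx - mean) since the
    # centered rx sums to zero, so one matrix product covers all n! cases
    ryp <- matrix(ry[perms], nrow = nrow(perms))
    rho_perm <- drop(ryp %*% (rx - mean(rx))) / ((n - 1) * sd(rx) * sd(ry))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    message(sprintf(
      "n = %d > %d: using t approximation for the Spearman p-value.",
      n, exact_max
    ))
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t approximation"
  }
  tibble(rho = rho, p_two_sided = p, n = n, method = method)
}

spearman_rho <- function(rx, ry) {
  sx <- sd(rx)
  sy <- sd(ry)
  if (sx == 0 || sy == 0) {
    abort("ranks are constant; rho is undefined.",
      class = "burstfish_domain_error"
    )
  }
  sum((rx - mean(rx)) * (ry - mean(ry))) / ((length(rx) - 1) * sx * sy)
}

# All n! permutations of 1..n as an (n! x n) matrix, built recursively.
permute_indices <- function(n) {
  if (n == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- permute_indices(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- c(k, rest[sub[i, ]])
      row <- row + 1L
    }
  }
  out
}

#' One-phase exponential decay regression
#'
#' Least-squares fit of the one-phase decay model
#' \deqn{y(x) = (y_0 - \mathrm{plateau})\,e^{-k x} + \mathrm{plateau}}
#' with rate constraint `k >= 0` (Levenberg-Marquardt), as used to describe
#' how noise (CV^2) and burstiness (Fano factor) fall with mean expression.
#' Starting values: `plateau = min(y)`, `y0 = max(y)`, and `k` from a
#' log-linear regression of `y - plateau` on `x`. `r_squared` is
#' `1 - SS_res / SS_tot`; for constant `y` (zero total sum of squares) the
#' fit is the constant itself and `r_squared` is defined as 1.
#'
#' @param data Optional data frame in which `x` and `y` are evaluated.
#' @param x,y Numeric vectors; at least 4 distinct `x` values.
#' @return Object of class `exp_decay_fit`: list with `y0`, `plateau`, `k`,
#'   `r_squared`, `fitted`, `data`. Has [tidy()], [glance()] and
#'   [autoplot()] methods.
#' @examples
#' x <- 0:4
#' y <- (5 - 1) * exp(-0.8 * x) + 1
#' fit_exp_decay(x = x, y = y)
#' @export
fit_exp_decay <- function(data = NULL, x, y) {
  if (!is.null(data)) {
    x <- rlang::eval_tidy(rlang::enquo(x), data)
    y <- rlang::eval_tidy(rlang::enquo(y), data)
  }
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.",
      class = "burstfish_domain_error"
    )
  }
  if (length(unique(x)) < 4L) {
    abort("need at least 4 distinct x values.",
      class = "burstfish_domain_error"
    )
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("`x` and `y` must be finite.", class = "burstfish_domain_error")
  }
  dat <- tibble(x = as.numeric(x), y = as.numeric(y))
  ss_tot <- sum((dat$y - mean(dat$y))^2)
  if (ss_tot == 0) {
    fit <- new_exp_decay_fit(
      y0 = dat$y[[1L]], plateau = dat$y[[1L]], k = 0,
      r_squared = 1, fitted = dat$y, data = dat
    )
    return(fit)
  }
  plateau0 <- min(dat$y)
  y00 <- max(dat$y)
  xr <- diff(range(dat$x))
  shifted <- dat$y - plateau0
  pos <- shifted > 0
  k0 <- if (sum(pos) >= 2L) {
    slope <- stats::coef(stats::lm(log(shifted[pos]) ~ dat$x[pos]))[[2L]]
    -slope
  } else {
    1 / xr
  }
  # keep the initial decay visible across the x range: k0 too small makes
  # the plateau gradient column vanish, too large kills the k column
  k0 <- min(max(k0, 0.2 / xr), 20 / xr)
  starts <- list(
    list(y0 = y00, plateau = plateau0, k = k0),
    list(y0 = min(dat$y), plateau = max(dat$y), k = k0),
    list(y0 = y00, plateau = mean(dat$y), k = 1 / xr)
  )
  fit <- NULL
  last_err <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ (y0 - plateau) * exp(-k * x) + plateau,
        data = dat,
        start = st,
        lower = c(y0 = -Inf, plateau = -Inf, k = 0),
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-15, ptol = 1e-15
        )
      ),
      error = function(e) {
        last_err <<- conditionMessage(e)
        NULL
      }
    )
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    abort(
      sprintf("one-phase decay fit failed to converge: %s", last_err),
      class = "burstfish_fit_error"
    )
  }
  est <- stats::coef(fit)
  fitted_y <- (est[["y0"]] - est[["plateau"]]) * exp(-est[["k"]] * dat$x) +
    est[["plateau"]]
  r2 <- 1 - sum((dat$y - fitted_y)^2) / ss_tot
  new_exp_decay_fit(
    y0 = est[["y0"]], plateau = est[["plateau"]], k = est[["k"]],
    r_squared = r2, fitted = fitted_y, data = dat
  )
}

new_exp_decay_fit <- function(y0, plateau, k, r_squared, fitted, data) {
  structure(
    list(
      y0 = y0, plateau = plateau, k = k, r_squared = r_squared,
      fitted = fitted, data = data
    ),
    class = "exp_decay_fit"
  )
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  cat(sprintf(
    "<exp_decay_fit>  y0 = %.4g  plateau = %.4g  k = %.4g  R^2 = %.4f\n",
    x$y0, x$plateau, x$k, x$r_squared
  ))
  invisible(x)
}

#' Predict from a one-phase decay fit
#' @param object An `exp_decay_fit`.
#' @param newdata Optional data frame with column `x`.
#' @param ... Unused.
#' @export
predict.exp_decay_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata$x
  (object$y0 - object$plateau) * exp(-object$k * x) + object$plateau
}
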