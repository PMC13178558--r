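#' MCMC configuration for ZINB burst inference
#'
#' Settings of the Metropolis-Hastings sampler. Defaults follow the
#' production protocol: 500,000 iterations, 100,000 burn-in, thinning by 100
#' (4,000 retained draws), per-coordinate Gaussian proposals with standard
#' deviation equal to 5% of the current parameter value. Because the
#' proposal scale depends on the current state the kernel is asymmetric;
#' with `hastings_correction = TRUE` (default) the acceptance probability
#' includes the kernel ratio q(theta | theta') / q(theta' | theta), which
#' preserves detailed balance. Setting it `FALSE` gives the plain Metropolis
#' rule. `min_proposal_sd` floors the proposal scale so a coordinate near 0
#' cannot freeze the chain.
#'
#' @param n_iter Total iterations (default 500000).
#' @param burn_in Discarded initial iterations (default 100000).
#' @param thin Keep every `thin`-th post-burn-in draw (default 100).
#' @param proposal_frac Proposal SD as a fraction of the current value
#'   (default 0.05).
#' @param min_proposal_sd Floor on the proposal SD (default 1e-4).
#' @param hastings_correction Apply the asymmetric-kernel correction
#'   (default `TRUE`).
#' @param seed Optional integer seed used by [run_mcmc()].
#' @return An object of class `mcmc_config`.
#' @examples
#' mcmc_config(n_iter = 50000, burn_in = 10000, thin = 25, seed = 1)
#' @export
mcmc_config <- function(n_iter = 500000, burn_in = 100000, thin = 100,
                        proposal_frac = 0.05, min_proposal_sd = 1e-4,
                        hastings_correction = TRUE, seed = NULL) {
  for (nm in c("n_iter", "burn_in", "thin", "proposal_frac",
    "min_proposal_sd")) {
    check_scalar_num(get(nm), nm)
  }
  if (burn_in < 0 || burn_in >= n_iter) {
    abort("need 0 <= burn_in < n_iter.", class = "burstfish_config_error")
  }
  if (thin < 1 || thin != floor(thin)) {
    abort("`thin` must be an integer >= 1.", class = "burstfish_config_error")
  }
  if (proposal_frac <= 0 || min_proposal_sd <= 0) {
    abort("`proposal_frac` and `min_proposal_sd` must be > 0.",
      class = "burstfish_config_error"
    )
  }
  structure(
    list(
      n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
      thin = as.integer(thin), proposal_frac = proposal_frac,
      min_proposal_sd = min_proposal_sd,
      hastings_correction = isTRUE(hastings_correction), seed = seed
    ),
    class = "mcmc_config"
  )
}

#' @export
print.mcmc_config <- function(x, ...) {
  cat(sprintf(
    "<mcmc_config>  %d iter / %d burn-in / thin %d  (retain %d)  proposal %.3g|x|  hastings %s\n",
    x$n_iter, x$burn_in, x$thin, (x$n_iter - x$burn_in) %/% x$thin,
    x$proposal_frac, x$hastings_correction
  ))
  invisible(x)
}

# Prior scale of the half-normal on r.
.sigma_r <- 20

extract_counts <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- validate_count_dataset(counts)$count
  }
  if (!is.numeric(counts) || length(counts) == 0L) {
    abort("`counts` must be a non-empty count dataset or integer vector.",
      class = "burstfish_domain_error"
    )
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("counts must be non-negative integers.",
      class = "burstfish_domain_error"
    )
  }
  as.numeric(counts)
}

#' Log posterior of the ZINB burst model
#'
#' Sum of the per-cell ZINB log-likelihood ([dzinb()]) and the log priors:
#' Uniform(0, 1) on `omega` and `p`, half-normal (mu = 0, sigma = 20,
#' positively truncated) on `r`. Returns `-Inf` outside the support.
#'
#' @param counts Count dataset tibble or non-negative integer vector.
#' @param params A [zinb_params] object or numeric `[omega, r, p]` (any
#'   numeric values accepted here; out-of-support values give `-Inf`).
#' @return A single log-density value (unnormalized posterior).
#' @examples
#' cts <- sample_zinb(zinb_params(0.5, 2, 0.7), 100, seed = 1)
#' log_posterior(cts, c(0.5, 2, 0.7))
#' @export
log_posterior <- function(counts, params) {
  k <- extract_counts(counts)
  theta <- if (inherits(params, "zinb_params")) {
    as.double(params)
  } else {
    as.numeric(params)
  }
  if (length(theta) != 3L || any(!is.finite(theta))) {
    abort("`params` must be three finite numbers [omega, r, p].",
      class = "burstfish_param_error"
    )
  }
  tab <- tabulate_counts(k)
  zinb_log_posterior_cpp(
    tab$k, tab$w, theta[[1L]], theta[[2L]], theta[[3L]], .sigma_r
  )
}

tabulate_counts <- function(k) {
  t <- table(k)
  list(k = as.numeric(names(t)), w = as.numeric(t))
}

default_init <- function(k) {
  m <- mean(k)
  v <- var(k)
  zf <- mean(k == 0)
  init <- c(0.5, 1, 0.5)
  if (is.finite(v) && v > m && m > 0) {
    p_hat <- 1 - m / v
    r_hat <- m^2 / (v - m)
    omega_hat <- min(max(zf - (1 - p_hat)^r_hat, 0.01), 0.99)
    cand <- c(omega_hat, r_hat, p_hat)
    if (all(is.finite(cand)) && cand[2] > 0 && cand[3] > 0 && cand[3] < 1) {
      init <- cand
    }
  }
  init
}

#' Metropolis-Hastings sampling of the ZINB posterior
#'
#' Samples theta = (omega, r, p) from the posterior of the zero-inflated
#' negative binomial burst model by a random-walk Metropolis-Hastings chain
#' with per-coordinate Gaussian proposals scaled to the current state (see
#' [mcmc_config()]). Proposals outside the support are rejected via a `-Inf`
#' posterior. The chain is initialized at a method-of-moments estimate
#' (fallback `[0.5, 1, 0.5]`), or at `init` if given. With a fixed seed the
#' chain is exactly reproducible.
#'
#' @param counts Non-empty count dataset tibble or integer vector. An
#'   all-zero dataset is valid (the posterior concentrates at omega -> 1).
#' @param config An [mcmc_config()].
#' @param init Optional starting point `[omega, r, p]`.
#' @return Object of class `posterior_chain`: list with `samples` (tibble
#'   `omega`, `r`, `p`, `log_post` of retained draws), `acceptance_rate`,
#'   `config`, `n_cells`, `init`. Has [tidy()], [glance()] and [autoplot()]
#'   methods; summarize with [summarize_posterior()].
#' @examples
#' cts <- sample_zinb(zinb_params(0.5, 2, 0.7), 200, seed = 1)
#' chain <- run_mcmc(cts, mcmc_config(5000, 1000, 10, seed = 1))
#' summarize_posterior(chain)
#' @export
run_mcmc <- function(counts, config = mcmc_config(), init = NULL) {
  if (!inherits(config, "mcmc_config")) {
    abort("`config` must be an mcmc_config.", class = "burstfish_config_error")
  }
  k <- extract_counts(counts)
  tab <- tabulate_counts(k)
  if (is.null(init)) {
    init <- default_init(k)
  }
  init <- as.numeric(init)
  if (length(init) != 3L) {
    abort("`init` must be [omega, r, p].", class = "burstfish_config_error")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  res <- mh_zinb_cpp(
    tab$k, tab$w, config$n_iter, config$burn_in, config$thin,
    config$proposal_frac, config$min_proposal_sd,
    config$hastings_correction, init, .sigma_r, 0
  )
  samples <- tibble(
    omega = res$samples[, 1L],
    r = res$samples[, 2L],
    p = res$samples[, 3L],
    log_post = res$log_post
  )
  structure(
    list(
      samples = samples,
      acceptance_rate = res$acceptance_rate,
      config = config,
      n_cells = length(k),
      init = init
    ),
    class = "posterior_chain"
  )
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat(sprintf(
    "<posterior_chain>  %d retained draws from %d cells; acceptance rate %.3f\n",
    nrow(x$samples), x$n_cells, x$acceptance_rate
  ))
  invisible(x)
}

#' Burst parameters from ZINB parameters
#'
#' Maps theta = (omega, r, p) to the biologically interpreted quantities:
#' repression `omega` (passthrough), burst size `b = p / (1 - p)` (mean
#' mRNAs per burst, the mean of a geometric burst under the NB law) and
#' burst frequency `f = r` (bursts per mRNA lifetime). The population mean
#' is `(1 - omega) * f * b`.
#'
#' @param params A [zinb_params] object or `[omega, r, p]` vector.
#' @return Named list `omega`, `b`, `f`.
#' @examples
#' burst_parameters(zinb_params(0.2, 2, 0.5)) # b = 1, f = 2
#' @export
burst_parameters <- function(params) {
  params <- as_zinb_params(params)
  if (params$p >= 1) {
    abort("p = 1 gives an infinite burst size.",
      class = "burstfish_domain_error"
    )
  }
  list(omega = params$omega, b = params$p / (1 - params$p), f = params$r)
}

#' Posterior summary: MAP and 95% credible intervals of burst parameters
#'
#' For each of repression `omega`, burst size `b = p / (1 - p)` and burst
#' frequency `f = r` (evaluated per retained draw before summarizing),
#' reports the maximum a posteriori estimate — the retained draw with the
#' highest stored log posterior — and the equal-tailed credible interval
#' (2.5th and 97.5th posterior percentiles). The raw `r` and `p` rows are
#' included as well for parameter-recovery checks.
#'
#' @param chain A `posterior_chain` from [run_mcmc()].
#' @param level Credible level; default 0.95.
#' @return Tibble with columns `term`, `map`, `conf.low`, `conf.high`, one
#'   row per term in (`omega`, `b`, `f`, `r`, `p`).
#' @export
summarize_posterior <- function(chain, level = 0.95) {
  if (!inherits(chain, "posterior_chain") || nrow(chain$samples) == 0L) {
    abort("`chain` must be a non-empty posterior_chain.",
      class = "burstfish_domain_error"
    )
  }
  s <- chain$samples
  i_map <- which.max(s$log_post)
  alpha <- (1 - level) / 2
  derived <- list(
    omega = s$omega,
    b = s$p / (1 - s$p),
    f = s$r,
    r = s$r,
    p = s$p
  )
  purrr::imap_dfr(derived, function(v, nm) {
    ci <- quantile(v, c(alpha, 1 - alpha), type = 7, names = FALSE)
    tibble(
      term = nm, map = v[[i_map]],
      conf.low = ci[[1L]], conf.high = ci[[2L]]
    )
  })
}

#' @rdname summarize_posterior
#' @param x A `posterior_chain`.
#' @param ... Unused.
#' @export
tidy.posterior_chain <- function(x, level = 0.95, ...) {
  summarize_posterior(x, level = level)
}

#' One-row summary of an MCMC run
#' @param x A `posterior_chain`.
#' @param ... Unused.
#' @return Tibble with `n_cells`, `n_retained`, `n_iter`, `acceptance_rate`,
#'   `max_log_post`.
#' @export
glance.posterior_chain <- function(x, ...) {
  tibble(
    n_cells = x$n_cells,
    n_retained = nrow(x$samples),
    n_iter = x$config$n_iter,
    acceptance_rate = x$acceptance_rate,
    max_log_post = max(x$samples$log_post)
  )
}

#' @rdname fit_exp_decay
#' @param x An `exp_decay_fit`.
#' @param ... Unused.
#' @export
tidy.exp_decay_fit <- function(x, ...) {
  tibble(
    term = c("y0", "plateau", "k"),
    estimate = c(x$y0, x$plateau, x$k)
  )
}

#' @rdname fit_exp_decay
#' @export
glance.exp_decay_fit <- function(x, ...) {
  tibble(r.squared = x$r_squared, nobs = nrow(x$data))
}
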