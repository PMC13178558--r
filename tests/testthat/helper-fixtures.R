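# Shared fixtures and independent oracles used across test files.

make_counts <- function(counts, strain = "s", condition_uM = 0) {
  tibble::tibble(
    cell_id = sprintf("c%03d", seq_along(counts)),
    strain = strain,
    condition_uM = condition_uM,
    count = as.integer(counts)
  )
}

# Independent ZINB pmf via stats::dnbinom (R's prob = 1 - p under the
# C(k+r-1,k) p^k (1-p)^r convention).
oracle_zinb_pmf <- function(k, omega, r, p) {
  ifelse(k == 0, omega, 0) + (1 - omega) * dnbinom(k, size = r, prob = 1 - p)
}

# Independent term-by-term log posterior: iid ZINB likelihood plus
# Uniform(0,1) priors on omega, p and half-normal(sigma = 20) on r.
oracle_log_posterior <- function(k, omega, r, p) {
  if (omega < 0 || omega > 1 || p <= 0 || p >= 1 || r <= 0) {
    return(-Inf)
  }
  sum(log(oracle_zinb_pmf(k, omega, r, p))) + log(2 * dnorm(r, 0, 20))
}

# Vectorized oracle over a data frame of (omega, r, p) grid points; sums the
# tabulated likelihood through stats::dnbinom, independent of the package's
# log-gamma implementation.
oracle_grid_log_posterior <- function(k, grid) {
  tab <- table(k)
  ku <- as.numeric(names(tab))
  w <- as.numeric(tab)
  lp <- log(2 * dnorm(grid$r, 0, 20))
  for (j in seq_along(ku)) {
    pm <- (1 - grid$omega) * dnbinom(ku[j], size = grid$r, prob = 1 - grid$p)
    if (ku[j] == 0) pm <- pm + grid$omega
    lp <- lp + w[j] * log(pm)
  }
  lp
}

# Closed-form ZINB variance (checked against brute-force pmf summation in
# test-zinb.R).
zinb_var_for_test <- function(omega, r, p) {
  m <- r * p / (1 - p)
  b <- p / (1 - p)
  (1 - omega) * m * (1 + b + omega * m)
}
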