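test_that("log posterior equals an independent term-by-term summation", {
  set.seed(71)
  cts <- sample_zinb(zinb_params(0.4, 2, 0.6), 10, seed = 71)
  for (i in 1:10) {
    th <- c(runif(1), abs(rnorm(1, 0, 5)) + 0.1, runif(1, 0.05, 0.95))
    expect_equal(
      log_posterior(cts, th),
      oracle_log_posterior(cts$count, th[1], th[2], th[3]),
      tolerance = 1e-10
    )
  }
})

test_that("log posterior is -Inf outside the prior support", {
  cts <- make_counts(c(0, 1, 2))
  expect_identical(log_posterior(cts, c(1.2, 2, 0.5)), -Inf)
  expect_identical(log_posterior(cts, c(0.5, -1, 0.5)), -Inf)
  expect_identical(log_posterior(cts, c(0.5, 2, 1.5)), -Inf)
})

test_that("doubling a dataset doubles the log-likelihood part", {
  k <- c(0, 0, 1, 3, 7)
  th <- c(0.3, 1.5, 0.6)
  lprior <- log(2 * dnorm(th[2], 0, 20))
  single <- log_posterior(make_counts(k), th) - lprior
  double <- log_posterior(make_counts(c(k, k)), th) - lprior
  expect_equal(double, 2 * single, tolerance = 1e-10)
})

test_that("mcmc_config validates and reports retained length", {
  cfg <- mcmc_config()
  expect_equal((cfg$n_iter - cfg$burn_in) %/% cfg$thin, 4000L)
  expect_error(mcmc_config(n_iter = 100, burn_in = 100),
    class = "burstfish_config_error")
  expect_error(mcmc_config(thin = 0), class = "burstfish_config_error")
  expect_error(mcmc_config(proposal_frac = 0),
    class = "burstfish_config_error")
})

test_that("default production protocol retains 4000 draws", {
  cts <- sample_zinb(zinb_params(0.3, 1.5, 0.6), 50, seed = 72)
  chain <- run_mcmc(cts, mcmc_config(seed = 72))
  expect_equal(nrow(chain$samples), 4000L)
  expect_gt(chain$acceptance_rate, 0)
  expect_lt(chain$acceptance_rate, 1)
  expect_true(all(is.finite(chain$samples$log_post)))
  expect_true(all(chain$samples$omega >= 0 & chain$samples$omega <= 1))
  expect_true(all(chain$samples$p > 0 & chain$samples$p < 1))
  expect_true(all(chain$samples$r > 0))
})

test_that("chains are reproducible and seed-sensitive", {
  cts <- sample_zinb(zinb_params(0.5, 2, 0.7), 300, seed = 73)
  cfg <- mcmc_config(20000, 5000, 10, seed = 7)
  a <- run_mcmc(cts, cfg)
  b <- run_mcmc(cts, cfg)
  expect_identical(a$samples, b$samples)
  expect_identical(a$acceptance_rate, b$acceptance_rate)
  cfg2 <- cfg
  cfg2$seed <- 8
  d <- run_mcmc(cts, cfg2)
  expect_false(identical(a$samples$omega, d$samples$omega))
})

test_that("shifting the log posterior by a constant leaves the chain alone", {
  cts <- sample_zinb(zinb_params(0.4, 2, 0.6), 200, seed = 74)
  tab <- table(cts$count)
  ku <- as.numeric(names(tab))
  w <- as.numeric(tab)
  init <- c(0.5, 1, 0.5)
  set.seed(99)
  base <- burstfish:::mh_zinb_cpp(ku, w, 20000L, 5000L, 10L, 0.05, 1e-4,
    TRUE, init, 20, 0)
  set.seed(99)
  shifted <- burstfish:::mh_zinb_cpp(ku, w, 20000L, 5000L, 10L, 0.05, 1e-4,
    TRUE, init, 20, 123.456)
  expect_identical(base$samples, shifted$samples)
  expect_identical(base$acceptance_rate, shifted$acceptance_rate)
  expect_equal(shifted$log_post - base$log_post,
    rep(123.456, length(base$log_post)))
})

test_that("an all-zero dataset drives repression toward 1", {
  cts <- make_counts(rep(0, 100))
  chain <- run_mcmc(cts, mcmc_config(20000, 5000, 10, seed = 75))
  est <- summarize_posterior(chain)
  expect_gt(est$map[est$term == "omega"], 0.5)
})

test_that("stored log posteriors agree with log_posterior()", {
  cts <- sample_zinb(zinb_params(0.3, 2, 0.6), 150, seed = 76)
  chain <- run_mcmc(cts, mcmc_config(5000, 1000, 20, seed = 76))
  idx <- c(1, 50, 200)
  for (i in idx) {
    th <- unlist(chain$samples[i, c("omega", "r", "p")])
    expect_equal(chain$samples$log_post[i], log_posterior(cts, th),
      tolerance = 1e-8)
  }
})

test_that("posterior summaries respect their definitions", {
  # degenerate chain: identical samples
  chain <- structure(
    list(
      samples = tibble::tibble(
        omega = rep(0.4, 10), r = rep(2, 10), p = rep(0.5, 10),
        log_post = rep(-12.3, 10)
      ),
      acceptance_rate = 0.5,
      config = mcmc_config(1000, 100, 10),
      n_cells = 10
    ),
    class = "posterior_chain"
  )
  est <- summarize_posterior(chain)
  expect_equal(est$map[est$term == "omega"], 0.4)
  expect_equal(est$map[est$term == "b"], 1) # p = 0.5 -> unit burst size
  expect_equal(est$conf.high - est$conf.low, rep(0, 5))
  # percentile containment
  set.seed(77)
  chain$samples$omega <- runif(10, 0.4, 0.6)
  est2 <- summarize_posterior(chain)
  expect_gte(est2$conf.low[est2$term == "omega"], 0.4)
  expect_lte(est2$conf.high[est2$term == "omega"], 0.6)
  expect_error(summarize_posterior(list()), class = "burstfish_domain_error")
})

test_that("burst parameter mapping and moment identity hold", {
  bp <- burst_parameters(zinb_params(0.2, 2, 0.5))
  expect_equal(bp$b, 1)
  expect_equal(bp$f, 2)
  expect_equal(bp$omega, 0.2)
  expect_error(burst_parameters(c(0.2, 2, 1)),
    class = "burstfish_param_error")
  om <- 0.4; r <- 1.5; p <- 0.65
  cts <- sample_zinb(zinb_params(om, r, p), 1e5, seed = 78)
  bp2 <- burst_parameters(c(om, r, p))
  true_mean <- (1 - om) * bp2$f * bp2$b
  se <- sqrt(zinb_var_for_test(om, r, p) / 1e5)
  expect_lt(abs(mean(cts$count) - true_mean), 3 * se)
})

test_that("MCMC recovers known parameters inside the credible intervals", {
  truth <- c(omega = 0.5, r = 2, p = 0.7)
  hits <- matrix(FALSE, 20, 3, dimnames = list(NULL, names(truth)))
  for (i in 1:20) {
    cts <- sample_zinb(zinb_params(truth[1], truth[2], truth[3]), 2000,
      seed = 1000 + i)
    chain <- run_mcmc(cts, mcmc_config(50000, 10000, 25, seed = 2000 + i))
    est <- summarize_posterior(chain)
    for (nm in names(truth)) {
      row <- est[est$term == nm, ]
      hits[i, nm] <- truth[nm] >= row$conf.low & truth[nm] <= row$conf.high
    }
  }
  expect_gte(sum(hits[, "omega"]), 17)
  expect_gte(sum(hits[, "r"]), 17)
  expect_gte(sum(hits[, "p"]), 17)
})

test_that("credible intervals calibrate across prior draws", {
  set.seed(81)
  n_rep <- 50
  hits <- matrix(FALSE, n_rep, 3,
    dimnames = list(NULL, c("omega", "r", "p")))
  # draw all truths and datasets from the model's own priors up front so the
  # chain seeds below cannot perturb the prior stream
  draws <- lapply(seq_len(n_rep), function(i) {
    om <- runif(1)
    r <- max(abs(rnorm(1, 0, 20)), 1e-6)
    p <- runif(1)
    list(truth = c(omega = om, r = r, p = p),
      cts = sample_zinb(zinb_params(om, r, p), 1000))
  })
  for (i in seq_len(n_rep)) {
    om <- draws[[i]]$truth[["omega"]]
    r <- draws[[i]]$truth[["r"]]
    p <- draws[[i]]$truth[["p"]]
    chain <- run_mcmc(draws[[i]]$cts,
      mcmc_config(150000, 30000, 50, seed = 3000 + i))
    est <- summarize_posterior(chain)
    for (nm in colnames(hits)) {
      row <- est[est$term == nm, ]
      truth <- c(omega = om, r = r, p = p)[nm]
      hits[i, nm] <- truth >= row$conf.low & truth <= row$conf.high
    }
  }
  # nominal 95% coverage; require >= 90% per parameter
  for (nm in colnames(hits)) {
    expect_gte(mean(hits[, nm]), 0.90)
  }
})

test_that("MCMC mode matches a brute-force grid argmax", {
  cts <- sample_zinb(zinb_params(0.3, 2, 0.6), 20, seed = 82)
  chain <- run_mcmc(cts, mcmc_config(200000, 40000, 20, seed = 83))
  est <- summarize_posterior(chain)
  grid <- expand.grid(
    omega = seq(0.01, 0.99, by = 0.01),
    r = seq(0.05, 15, by = 0.05),
    p = seq(0.01, 0.99, by = 0.01)
  )
  lp <- oracle_grid_log_posterior(cts$count, grid)
  best <- grid[which.max(lp), ]
  sds <- vapply(chain$samples[c("omega", "r", "p")], sd, numeric(1))
  expect_lt(abs(est$map[est$term == "omega"] - best$omega),
    max(2 * sds["omega"], 0.02))
  expect_lt(abs(est$map[est$term == "r"] - best$r), max(2 * sds["r"], 0.1))
  expect_lt(abs(est$map[est$term == "p"] - best$p),
    max(2 * sds["p"], 0.02))
})

test_that("ZINB fit to bursty telegraph counts recovers the burst size", {
  tp <- telegraph_params(k_on = 0.2, k_off = 20, k_tx = 200, k_deg = 1)
  cts <- simulate_telegraph(tp, 3000, t_end = 12, seed = 84)
  chain <- run_mcmc(cts, mcmc_config(50000, 10000, 25, seed = 85))
  est <- summarize_posterior(chain)
  b_map <- est$map[est$term == "b"]
  b_true <- tp$k_tx / tp$k_off
  expect_lt(abs(b_map - b_true) / b_true, 0.25)
})
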