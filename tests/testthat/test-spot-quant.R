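test_that("false-positive threshold follows the (n-1)q percentile rule", {
  expect_equal(fp_threshold(rep(7, 25)), 7)
  expect_equal(fp_threshold(1:1000), 999.001)
  expect_equal(fp_threshold(42), 42)
  # order must not matter
  expect_equal(fp_threshold(sample(1:1000)), 999.001)
  expect_error(fp_threshold(numeric()), class = "burstfish_domain_error")
})

test_that("mixture fit recovers a single tight intensity cluster", {
  set.seed(21)
  x <- rnorm(1000, mean = 100, sd = 5)
  mix <- fit_intensity_mixture(x, n_components = 1)
  expect_equal(nrow(mix), 1L)
  expect_equal(sum(mix$weight), 1, tolerance = 1e-9)
  expect_lt(abs(mix$mean[1] - 100), 3 * 5 / sqrt(1000))
})

test_that("mixture fit separates two quantal components", {
  set.seed(22)
  x <- c(rnorm(2000, 100, 8), rnorm(2000, 200, 8))
  mix <- fit_intensity_mixture(x, n_components = 2)
  expect_equal(nrow(mix), 2L)
  expect_true(all(diff(mix$mean) > 0))
  expect_lt(abs(mix$mean[1] - 100), 2)
  expect_lt(abs(mix$mean[2] - 200), 2)
  expect_equal(sum(mix$weight), 1, tolerance = 1e-9)
})

test_that("mixture fit refuses too few points", {
  expect_error(fit_intensity_mixture(rnorm(5), n_components = 2),
    class = "burstfish_fit_error")
})

test_that("quantification rule: threshold, divide, round", {
  spots <- tibble::tibble(
    spot_id = c("s1", "s2", "s3", "s4"),
    cell_id = c("a", "a", "b", "b"),
    intensity = c(95, 210, 10, 12),
    peak_height = c(1, 1, 1, 1)
  )
  tab <- spot_table(spots, cells = c("a", "b", "empty"))
  calib <- intensity_calibration(
    fp_threshold = 20,
    mixture = tibble::tibble(weight = 1, mean = 100, sd = 5)
  )
  cts <- quantify_counts(tab, calib)
  expect_equal(cts$count[cts$cell_id == "a"], 3L) # round(305 / 100)
  expect_equal(cts$count[cts$cell_id == "b"], 0L) # both sub-threshold
  expect_equal(cts$count[cts$cell_id == "empty"], 0L) # silent cell
  bad <- calib
  bad$unit_intensity <- 0
  expect_error(quantify_counts(tab, bad), class = "burstfish_param_error")
})

test_that("raising the threshold never increases a count", {
  cts <- sample_zinb(zinb_params(0.2, 2, 0.6), 200, seed = 31)
  tab <- generate_spot_table(cts, unit_intensity = 100, intensity_cv = 0.1,
    seed = 32)
  mixture <- tibble::tibble(weight = 1, mean = 100, sd = 10)
  thresholds <- c(0, 30, 60, 90, 120)
  counts_by_thr <- lapply(thresholds, function(thr) {
    quantify_counts(tab, intensity_calibration(thr, mixture))$count
  })
  for (i in seq_len(length(thresholds) - 1)) {
    expect_true(all(counts_by_thr[[i + 1]] <= counts_by_thr[[i]]))
  }
})

test_that("spot order does not affect counts", {
  cts <- sample_zinb(zinb_params(0.2, 2, 0.6), 100, seed = 33)
  tab <- generate_spot_table(cts, seed = 34)
  calib <- intensity_calibration(
    fp_threshold(tab$control_intensities),
    tibble::tibble(weight = 1, mean = 100, sd = 5)
  )
  shuffled <- tab
  set.seed(35)
  shuffled$spots <- shuffled$spots[sample(nrow(shuffled$spots)), ]
  expect_equal(quantify_counts(tab, calib), quantify_counts(shuffled, calib))
})

test_that("spot generator honours its contracts", {
  cts <- make_counts(c(0, 3))
  tab <- generate_spot_table(cts, unit_intensity = 100, intensity_cv = 0.05,
    n_control = 0, seed = 41)
  expect_equal(length(tab$control_intensities), 0L)
  expect_false("c001" %in% tab$spots$cell_id) # count 0 emits no spots
  sum3 <- sum(tab$spots$intensity[tab$spots$cell_id == "c002"])
  expect_lt(abs(sum3 - 300), 3 * 0.05 * 100 * sqrt(3))
  expect_error(
    generate_spot_table(cts, unit_intensity = -1),
    class = "burstfish_param_error"
  )
  expect_error(
    generate_spot_table(cts, intensity_cv = 0.7),
    class = "burstfish_param_error"
  )
})

test_that("sum of three unit spots concentrates around three units", {
  # repeat the single-cell spec arithmetic across seeds to guard the
  # generator's intensity scaling, not a single draw
  devs <- vapply(1:20, function(s) {
    tab <- generate_spot_table(make_counts(3), unit_intensity = 100,
      intensity_cv = 0.05, n_control = 0, seed = 100 + s)
    sum(tab$spots$intensity) - 300
  }, numeric(1))
  expect_lt(mean(abs(devs) <= 3 * 0.05 * 100 * sqrt(3)), 1 + 1e-9)
  expect_gt(mean(abs(devs) <= 3 * 0.05 * 100 * sqrt(3)), 0.85)
})

test_that("end-to-end spot pipeline recovers true counts", {
  truth <- sample_zinb(zinb_params(0.3, 2, 0.5), 1000, seed = 51)
  tab <- generate_spot_table(truth, unit_intensity = 100,
    intensity_cv = 0.10, n_control = 1000,
    control_scale = 12, seed = 52)
  calib <- calibrate_intensities(tab, n_components = 1)
  expect_lt(calib$fp_threshold, 50) # control sits below half a unit
  got <- quantify_counts(tab, calib)
  recovered <- mean(got$count[match(truth$cell_id, got$cell_id)] ==
    truth$count)
  expect_gte(recovered, 0.99)
})
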