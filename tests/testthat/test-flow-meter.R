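test_that("total angle equals the smallest covering arc (brute-force oracle)", {
  proto <- sampling_protocol(10, 1)
  set.seed(123)
  for (i in 1:40) {
    ph <- switch(1 + i %% 3,
                 runif(10, -pi, pi),
                 rnorm(10, 0, 0.3),
                 cumsum(rnorm(10, 0, 1)))
    tr <- tibble::tibble(time_s = 0:9, phi_rad = ph)
    expect_equal(total_angle(tr, proto),
                 brute_circular_range(ph) * 180 / pi, tolerance = 1e-10)
  }
})

test_that("total angle handles the canonical cases", {
  proto <- sampling_protocol(4, 5)
  tr <- tibble::tibble(time_s = c(0, 5, 10, 15),
                       phi_rad = c(0, pi / 2, pi, 3 * pi / 2))
  expect_equal(total_angle(tr, proto), 270)
  const <- tibble::tibble(time_s = c(0, 5, 10, 15), phi_rad = rep(1.1, 4))
  expect_equal(total_angle(const, proto), 0)
  dense <- tibble::tibble(time_s = seq(0, 15, length.out = 1000),
                          phi_rad = seq(-pi, pi, length.out = 1000))
  expect_gt(total_angle(dense, sampling_protocol(1000, 15 / 999)), 359)
})

test_that("total angle is a set statistic: rotation and order invariant", {
  proto <- sampling_protocol(8, 1)
  set.seed(5)
  ph <- rnorm(8, 0, 0.8)
  base <- total_angle(tibble::tibble(time_s = 0:7, phi_rad = ph), proto)
  rot <- total_angle(tibble::tibble(time_s = 0:7, phi_rad = ph + 2.345), proto)
  perm <- total_angle(tibble::tibble(time_s = 0:7, phi_rad = sample(ph)), proto)
  expect_equal(rot, base, tolerance = 1e-10)
  expect_equal(perm, base, tolerance = 1e-10)
})

test_that("trajectories shorter than the protocol are refused", {
  tr <- tibble::tibble(time_s = seq(0, 100, 5), phi_rad = 0)
  expect_error(total_angle(tr, sampling_protocol(30, 5)),
               class = "windsock_coverage_error")
})

test_that("calibration is deterministic in the seed and records per-rod angles", {
  grid <- c(0.2, 1)
  c1 <- build_calibration(grid, n_rods = 4, seed = 3)
  c2 <- build_calibration(grid, n_rods = 4, seed = 3)
  expect_identical(c1$curve, c2$curve)
  expect_identical(c1$rods$phi_deg, c2$rods$phi_deg)
  expect_equal(nrow(c1$rods), 8)
  expect_true(all(c1$rods$phi_deg >= 0 & c1$rods$phi_deg <= 360))
})

test_that("mean total angle decreases from weak to strong flow", {
  cal <- build_calibration(c(0.05, 0.4, 2), n_rods = 8, seed = 4)
  expect_true(all(diff(cal$curve$phi_mean_deg) < 0))
})

test_that("rod-length heterogeneity knob perturbs but preserves the trend", {
  cal <- build_calibration(c(0.1, 1.6), n_rods = 6, seed = 6,
                           length_dist = function(n) runif(n, 4, 6))
  expect_lt(cal$curve$phi_mean_deg[2], cal$curve$phi_mean_deg[1])
})

test_that("shear estimation inverts the curve and respects its range", {
  grid <- c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6)
  mu <- c(300, 250, 180, 110, 60, 35)
  cal <- mock_calibration(grid, mu, sd = rep(12, 6))
  # observation at a grid mean recovers (about) that grid stress
  est <- estimate_shear(cal$curve$phi_mean_deg[4], 15, cal, seed = 2)
  expect_equal(est$tau_hat, 0.4, tolerance = 0.05)
  expect_false(est$saturated)
  expect_true(est$ci_lower <= est$tau_hat && est$tau_hat <= est$ci_upper)
  # interpolation between grid points stays bracketed
  est2 <- estimate_shear(145, 15, cal, seed = 2)
  expect_true(est2$tau_hat > 0.2 && est2$tau_hat < 0.4)
  # above the plateau: saturation flag at the lowest calibrated stress
  expect_warning(est3 <- estimate_shear(330, 15, cal, seed = 2),
                 class = "windsock_saturation_warning")
  expect_true(est3$saturated)
  expect_equal(est3$tau_hat, grid[1])
  # below the calibrated range: dynamic-range error
  expect_error(estimate_shear(5, 15, cal, seed = 2),
               class = "windsock_extrapolation_error")
})

test_that("tidiers expose calibration and estimate results as tibbles", {
  cal <- mock_calibration(c(0.1, 0.4, 1), c(250, 120, 50), rep(10, 3))
  expect_s3_class(tidy(cal), "tbl_df")
  expect_named(glance(estimate_shear(120, 15, cal, seed = 1)),
               c("estimate", "conf.low", "conf.high", "saturated",
                 "phi_obs_deg", "n_observed"))
})
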