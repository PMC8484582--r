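test_that("trajectories are reproducible bit-for-bit from seed and params", {
  rod <- default_rod
  t1 <- simulate_trajectory(rod, 1e-6, 30, seed = 11, record_dt_s = 0.5)
  t2 <- simulate_trajectory(rod, 1e-6, 30, seed = 11, record_dt_s = 0.5)
  expect_identical(t1$phi_rad, t2$phi_rad)
  t3 <- simulate_trajectory(rod, 1e-6, 30, seed = 12, record_dt_s = 0.5)
  expect_false(identical(t1$phi_rad, t3$phi_rad))
})

test_that("zero-flow angular variance grows as 2 D t", {
  rod <- default_rod
  D <- rot_diffusion(rod)
  tr <- simulate_trajectory(rod, 0, 4000, seed = 21, dt_s = 0.05,
                            record_dt_s = 0.5)
  for (lag_steps in c(1, 4)) {
    inc <- diff(tr$phi_rad, lag = lag_steps)
    inc <- inc[seq(1, length(inc), by = lag_steps)]  # non-overlapping
    expect_equal(var(inc), 2 * D * 0.5 * lag_steps, tolerance = 0.08)
  }
})

test_that("near-zero temperature gives monotone overdamped relaxation", {
  rod <- default_rod
  tr <- simulate_trajectory(rod, kappa_to_velocity(rod, 5), 20, seed = 1,
                            phi0_rad = 0.5, temperature_K = 1e-12,
                            dt_s = 0.01, record_dt_s = 0.1)
  expect_true(all(diff(tr$phi_rad) <= 1e-6))
  expect_lt(abs(tr$phi_rad[nrow(tr)]), 0.05)
})

test_that("reversing the flow moves the stationary mode from 0 to pi", {
  rod <- default_rod
  u <- kappa_to_velocity(rod, 5)
  fwd <- draw_stationary(rod, 5, 2000, seed = 31)
  D <- rot_diffusion(rod)
  bwd <- sample_stationary(rod, -u, 2000, lag_s = 1 / (5 * D), seed = 31,
                           dt_s = 0.02 / (5 * D), burn_in_s = 4 / (5 * D),
                           phi0_rad = pi)
  expect_gt(mean(cos(fwd)), 0.85)   # concentrated at 0
  expect_lt(mean(cos(bwd)), -0.85)  # concentrated at pi
})

test_that("time steps beyond the stability bound are refused", {
  rod <- default_rod
  u <- kappa_to_velocity(rod, 50)
  a <- 50 * rot_diffusion(rod)
  expect_error(simulate_trajectory(rod, u, 10, seed = 1, dt_s = 1 / a),
               class = "windsock_unstable_step")
})

test_that("noise conventions differ by a factor two in increment variance", {
  rod <- default_rod
  D <- rot_diffusion(rod)
  t_fdt <- simulate_trajectory(rod, 0, 400, seed = 5, dt_s = 0.1)
  t_half <- simulate_trajectory(rod, 0, 400, seed = 5, dt_s = 0.1,
                                noise_convention = "as_printed")
  expect_equal(var(diff(t_half$phi_rad)) / var(diff(t_fdt$phi_rad)), 0.5,
               tolerance = 1e-12)  # same normal draws, scaled
  expect_equal(var(diff(t_fdt$phi_rad)), 2 * D * 0.1, tolerance = 0.05)
})

test_that("population initial angles are uniform and independently seeded", {
  pop <- sample_population(2000, default_rod, 0, 0.2, seed = 7, dt_s = 0.1,
                           record_dt_s = 0.2)
  phi0 <- attr(pop, "params")$phi0_rad
  expect_length(phi0, 2000)
  ct <- table(cut(phi0, seq(-pi, pi, length.out = 21)))
  expect_gt(stats::chisq.test(ct)$p.value, 0.01)
  first <- pop |> dplyr::group_by(rod) |> dplyr::slice_min(time_s) |>
    dplyr::pull(phi_rad)
  expect_equal(sort(first), sort(phi0))
})

test_that("long-run wrapped angles match the stationary law (moderate n)", {
  # full-scale goodness of fit lives in the acceptance suite; this guards
  # the sampler at reduced n
  for (kap in c(0.5, 2)) {
    s <- draw_stationary(default_rod, kap, 4000, seed = 40 + kap)
    expect_lt(ks_vs_stationary(s, kap), 0.035)
  }
})

test_that("hemisphere dynamics: equilibrium solid angle at U = 0 and
           wall-hugging polar angle under strong flow", {
  rod <- default_rod
  D <- rot_diffusion(rod)
  sph <- simulate_spherical(rod, 0, 600, seed = 8, dt_s = 0.01,
                            record_dt_s = 2)
  # p(theta) ~ sin(theta) on the hemisphere: cos(theta) ~ Uniform(0, 1)
  ct <- cos(sph$theta_rad[sph$time_s > 20])
  expect_gt(suppressWarnings(
    stats::ks.test(ct, "punif")$p.value), 1e-4)
  # near theta = pi/2 the equilibrium polar deviation is half-normal with
  # sigma = 1/sqrt(kappa): E[pi/2 - theta] = sqrt(2/(pi kappa))
  for (kap in c(10, 30)) {
    strong <- simulate_spherical(rod, kappa_to_velocity(rod, kap), 120,
                                 seed = 9, dt_s = 0.005, record_dt_s = 0.5)
    dev <- pi / 2 - mean(strong$theta_rad[strong$time_s > 10])
    expect_equal(dev, sqrt(2 / (pi * kap)), tolerance = 0.3)
  }
})
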