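test_that("presets carry the study constants", {
  p <- windsock_presets()
  expect_equal(p$persistence_length_um, 8.7)
  expect_equal(p$channels$`VI_0.4`$height_mm, 0.4)
  expect_equal(p$channels$`VI_0.5`$height_mm, 0.54)
  expect_equal(p$protocol, list(n_frames = 30, interval_s = 5))
  expect_equal(p$decay$seeds$b_per_h, 3.3)
  expect_equal(p$decay$nanotubes$b_per_h, 0.52)
  expect_equal(p$spytag, list(k_on_M_s = 1400, conc_M = 64e-12,
                              n_receptors = 1e4))
  expect_equal(p$shear_grid_confocal, c(0, 0.05, 0.2, 1))
  expect_equal(p$n_rods_per_stress, 15)
  expect_equal(p$n_cells_decay, 6)
})

test_that("angle generator keeps ground truth beside noisy readings", {
  d0 <- gen_angle_dataset(0.4, n_rods = 3, noise_sd_deg = 0, seed = 11)
  expect_equal(d0$frames$phi_obs_rad, wrap_angle(d0$frames$phi_true_rad))
  d3 <- gen_angle_dataset(0.4, n_rods = 3, noise_sd_deg = 3, seed = 11)
  expect_identical(d3$frames$phi_true_rad, d0$frames$phi_true_rad)
  err <- wrap_angle(d3$frames$phi_obs_rad - d3$frames$phi_true_rad)
  expect_equal(sd(err) * 180 / pi, 3, tolerance = 0.4)
  d3b <- gen_angle_dataset(0.4, n_rods = 3, noise_sd_deg = 3, seed = 11)
  expect_identical(d3$frames, d3b$frames)
  expect_equal(d3$manifest$shear_dyn_cm2, 0.4)
})

test_that("angular measurement noise barely perturbs the total angle", {
  d <- gen_angle_dataset(0.4, n_rods = 40, noise_sd_deg = 3, seed = 12)
  proto <- sampling_protocol()
  diffs <- sapply(split(d$frames, d$frames$rod), function(f) {
    f$rod <- NULL
    clean <- total_angle(f, proto, phi_col = "phi_true_rad")
    noisy <- total_angle(f, proto, phi_col = "phi_obs_rad")
    abs(noisy - clean)
  })
  expect_lt(median(diffs), 10)
})

test_that("decay generator is exact when noiseless and normalised at t = 0", {
  t <- seq(0, 70, 10) / 60
  d0 <- gen_decay_dataset(3.3, times_h = t, noise_sd = 0, n_cells = 2,
                          seed = 13)
  expect_equal(d0$fraction, rep(exp(-3.3 * t), 2), tolerance = 1e-12)
  dn <- gen_decay_dataset(0.52, times_h = seq(0, 3, 0.25), noise_sd = 0.02,
                          n_cells = 6, seed = 14)
  expect_true(all(dn$fraction[dn$time_h == 0] == 1))
  expect_true(all(dn$fraction >= 0))
  expect_equal(attr(dn, "manifest")$b_per_h, 0.52)
})

test_that("decay generator feeds the fitter back its own rate", {
  d <- gen_decay_dataset(3.3, seed = 15)  # default: seed-series design
  fit <- fit_decay(d)
  expect_equal(fit$b, 3.3, tolerance = 0.15)
  expect_equal(fit$a, 1, tolerance = 0.05)
})

test_that("coloc generator hits its target fraction in the extremes", {
  mask <- ellipse_mask(30, 20, 0.2)
  d1 <- gen_coloc_dataset(1, 0.2, mask, n_cells = 1, n_seeds = 80, seed = 16)
  expect_equal(coloc_fraction(d1[d1$channel == "seed", ],
                              d1[d1$channel == "antibody", ], 0.5), 1)
  # at fraction 0 the observed rate is the Poisson baseline
  lam <- 0.5
  d0 <- gen_coloc_dataset(0, lam, rect_mask(50, 50, 0.25), n_cells = 1,
                          n_seeds = 2000, seed = 17)
  expect_equal(coloc_fraction(d0[d0$channel == "seed", ],
                              d0[d0$channel == "antibody", ], 0.5),
               1 - exp(-lam * pi * 0.25), tolerance = 0.1)
  expect_true(all(!d0$colocalized[d0$channel == "seed"]))
  expect_error(gen_coloc_dataset(1.4, 1), class = "windsock_domain_error")
})

test_that("cohort-level recovery of a planted colocalized fraction", {
  mask <- ellipse_mask(30, 20, 0.2)
  d <- gen_coloc_dataset(0.76, 0.3, mask, n_cells = 12, n_seeds = 120,
                         seed = 18)
  fr <- sapply(split(d, d$cell), function(cell)
    coloc_fraction(cell[cell$channel == "seed", ],
                   cell[cell$channel == "antibody", ], 0.5))
  s <- per_cell_summary(fr)
  # observed fraction = planted fraction + chance hits among the (1 - 0.76)
  expected <- 0.76 + 0.24 * (1 - exp(-0.3 * pi * 0.25))
  expect_true(s$ci_lower - 0.05 < expected && expected < s$ci_upper + 0.05)
})
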