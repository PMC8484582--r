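test_that("attachment rate is the pseudo-first-order product, per hour", {
  expect_equal(attachment_rate(1400, 0, 1e4), 0)
  # slow covalent-tag scenario: order one event per cell per hour
  expect_equal(attachment_rate(1400, 64e-12, 1e4), 1400 * 64e-12 * 1e4 * 3600,
               tolerance = 1e-12)
  expect_equal(attachment_rate(1400, 64e-12, 1e4), 3.2, tolerance = 0.01)
  # antibody/DNA-speed scenario: thousands per hour
  expect_equal(attachment_rate(1e6, 64e-12, 1e4), 2304, tolerance = 1e-9)
  # linear in each argument
  base <- attachment_rate(1e5, 1e-11, 1e3)
  expect_equal(attachment_rate(3e5, 1e-11, 1e3), 3 * base)
  expect_equal(attachment_rate(1e5, 5e-11, 1e3), 5 * base)
  expect_equal(attachment_rate(1e5, 1e-11, 7e3), 7 * base)
  # optional diffusion ceiling caps the rate constant
  expect_lt(attachment_rate(1e9, 1e-11, 1e3, k_on_cap_M_s = 1e6),
            attachment_rate(1e9, 1e-11, 1e3))
})

test_that("equilibrium occupancy is Langmuir in C and Kd", {
  expect_equal(equilibrium_occupancy(1e-9, 1e-9), 0.5)
  expect_equal(equilibrium_occupancy(64e-12, 1e-9), 64 / 1064,
               tolerance = 1e-12)
  expect_equal(equilibrium_occupancy(16e-12, 1e-13), 0.994, tolerance = 1e-3)
  cs <- 10^seq(-13, -7, by = 0.5)
  occ <- equilibrium_occupancy(cs, 1e-9)
  expect_true(all(occ >= 0 & occ <= 1))
  expect_true(all(diff(occ) > 0))
  expect_true(all(diff(equilibrium_occupancy(1e-10, 10^seq(-12, -8))) < 0))
  expect_error(equilibrium_occupancy(0, 0), class = "windsock_undefined_error")
})

test_that("multivalent retention follows the all-sites-release power law", {
  expect_equal(multivalent_retention(1e-3, 1, 5), 1e-3)
  expect_equal(multivalent_retention(1e-3, 4, 0), 1e-3)  # no rebinding, no avidity
  # p_release = 0.1 at rebind = 9 k_off: six sites give a 1e5-fold reduction
  expect_equal(multivalent_retention(1e-3, 6, 9e-3), 1e-3 * 0.1^5,
               tolerance = 1e-12)
  ks <- sapply(1:8, function(n) multivalent_retention(1e-3, n, 5e-3))
  expect_true(all(diff(ks) < 0))
  expect_true(all(diff(sapply(c(0, 1e-3, 1e-2, 1e-1), function(r)
    multivalent_retention(1e-3, 4, r))) < 0))
})

test_that("duplex Kd is the Boltzmann factor of the formation free energy", {
  expect_equal(duplex_kd(0), 1)
  expect_equal(duplex_kd(-17, 310), exp(-17 / (1.98720425864e-3 * 310)),
               tolerance = 1e-12)
  expect_lt(duplex_kd(-17, 310), 1e-12 * 1.1)  # sub-picomolar regime
  expect_true(all(diff(duplex_kd(seq(-20, -5, by = 1))) > 0))
})

test_that("decay fitting recovers a noiseless exponential exactly", {
  t <- seq(0, 2, by = 0.25)
  fit <- fit_decay(tibble::tibble(time_h = t, fraction = exp(-2 * t)))
  expect_equal(fit$a, 1, tolerance = 1e-8)
  expect_equal(fit$b, 2, tolerance = 1e-8)
  expect_equal(fit$method, "nls")
})

test_that("a constant series fits with zero decay rate", {
  fit <- fit_decay(tibble::tibble(time_h = 0:5, fraction = rep(1, 6)))
  expect_equal(fit$b, 0, tolerance = 1e-8)
  expect_equal(fit$a, 1, tolerance = 1e-8)
})

test_that("decay fit is scale-equivariant in the amplitude", {
  set.seed(10)
  t <- seq(0, 1.2, by = 0.15)
  y <- exp(-1.7 * t) + rnorm(length(t), 0, 0.01)
  y[1] <- 1
  f1 <- fit_decay(tibble::tibble(time_h = t, fraction = y))
  f2 <- fit_decay(tibble::tibble(time_h = t, fraction = 3 * y))
  expect_equal(f2$a, 3 * f1$a, tolerance = 1e-6)
  expect_equal(f2$b, f1$b, tolerance = 1e-6)
})

test_that("rate recovery is nearly unbiased at the persistence-assay design", {
  # 8 time points over 70 min, sd 0.02, 6 cells, truth b = 3.3/h
  bhat <- sapply(1:60, function(i) {
    d <- gen_decay_dataset(3.3, times_h = seq(0, 70, 10) / 60,
                           noise_sd = 0.02, n_cells = 6, seed = 1000 + i)
    fit_decay(d)$b
  })
  expect_lt(abs(mean(bhat) / 3.3 - 1), 0.03)
})

test_that("fit errors are informative for malformed series", {
  expect_error(fit_decay(tibble::tibble(time_h = c(0, 1), fraction = c(1, 0.5))),
               class = "windsock_domain_error")
  expect_error(fit_decay(tibble::tibble(time_h = c(1, 2, 3),
                                        fraction = c(0.9, 0.8, 0.7))),
               class = "windsock_domain_error")
})

test_that("decay tidiers report both parameters with intervals", {
  t <- seq(0, 2, by = 0.25)
  fit <- fit_decay(tibble::tibble(time_h = t,
                                  fraction = exp(-t) + c(0, rnorm(8, 0, 0.01))))
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b"))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  expect_equal(glance(fit)$nobs, 9)
})
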