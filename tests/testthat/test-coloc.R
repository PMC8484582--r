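test_that("colocalized fraction handles degenerate patterns", {
  pts <- tibble::tibble(x_um = runif(20, 0, 10), y_um = runif(20, 0, 10))
  expect_equal(coloc_fraction(pts, pts, 0.1), 1)
  expect_equal(coloc_fraction(pts, pts[0, ], 0.5), 0)
  expect_error(coloc_fraction(pts[0, ], pts, 0.5),
               class = "windsock_undefined_error")
  expect_error(coloc_fraction(pts, pts, -1), class = "windsock_domain_error")
})

test_that("fraction is monotone non-decreasing in the radius", {
  set.seed(2)
  seeds <- tibble::tibble(x_um = runif(300, 0, 20), y_um = runif(300, 0, 20))
  abs_ <- tibble::tibble(x_um = runif(200, 0, 20), y_um = runif(200, 0, 20))
  fr <- sapply(c(0.1, 0.3, 0.5, 1, 2), function(r)
    coloc_fraction(seeds, abs_, r))
  expect_true(all(diff(fr) >= 0))
})

test_that("neighbour search agrees with brute-force distances", {
  set.seed(3)
  seeds <- tibble::tibble(x_um = runif(80, 0, 12), y_um = runif(80, 0, 12))
  abs_ <- tibble::tibble(x_um = runif(60, 0, 12), y_um = runif(60, 0, 12))
  r <- 0.8
  d2 <- outer(seeds$x_um, abs_$x_um, "-")^2 + outer(seeds$y_um, abs_$y_um, "-")^2
  expect_equal(coloc_fraction(seeds, abs_, r), mean(apply(d2, 1, min) <= r^2))
})

test_that("Poisson antibodies give the void-probability fraction", {
  # P(>= 1 antibody within r) = 1 - exp(-lambda pi r^2); big mask, modest n
  mask <- rect_mask(60, 60, 0.25)
  lam <- 0.6; r <- 0.5
  set.seed(4)
  abs_ <- sample_in_mask(rpois(1, lam * mask_area(mask)), mask)
  seeds <- sample_in_mask(3000, mask)
  expected <- 1 - exp(-lam * pi * r^2)
  expect_equal(coloc_fraction(seeds, abs_, r), expected, tolerance = 0.12)
})

test_that("randomized null is seeded, bounded, and extreme for planted patterns", {
  mask <- ellipse_mask(30, 20, 0.2)
  d <- gen_coloc_dataset(1, 0.3, mask, n_cells = 1, n_seeds = 60, seed = 5)
  seeds <- d[d$channel == "seed", ]
  abs_ <- d[d$channel == "antibody", ]
  res <- randomized_null(seeds, abs_, mask, radius_um = 0.5, n_perm = 199,
                         seed = 6)
  res2 <- randomized_null(seeds, abs_, mask, radius_um = 0.5, n_perm = 199,
                          seed = 6)
  expect_identical(res$null_fractions, res2$null_fractions)
  expect_equal(res$observed, 1)
  expect_equal(res$p_value, 1 / 200)  # fully colocalized: minimal p
  expect_true(all(res$null_fractions >= 0 & res$null_fractions <= 1))
  expect_error(randomized_null(seeds, abs_, mask, n_perm = 50),
               class = "windsock_domain_error")
})

test_that("cohort summary reproduces t-interval arithmetic", {
  expect_equal(per_cell_summary(c(0.7, 0.8))$mean, 0.75)
  same <- per_cell_summary(rep(0.6, 5))
  expect_equal(same$ci_half, 0)
  # 12 cells with sd 0.07: half-width ~ 2.201 * 0.07 / sqrt(12) ~ 0.044,
  # the scale of a +/-4 percentage-point cohort interval
  set.seed(7)
  f <- rnorm(12, 0.76, 0.07)
  s <- per_cell_summary(f)
  expect_equal(s$ci_half, qt(0.975, 11) * sd(f) / sqrt(12), tolerance = 1e-12)
  expect_error(per_cell_summary(0.5), class = "windsock_domain_error")
})

test_that("masks report area and contain their samples", {
  m <- ellipse_mask(30, 20, 0.1)
  expect_equal(mask_area(m), pi * 15 * 10, tolerance = 0.01)
  pts <- sample_in_mask(500, m, seed = 8)
  expect_true(all(in_mask(pts, m)))
  expect_error(sample_in_mask(5, ellipse_mask(0.05, 0.05, 0.1)),
               class = "windsock_placement_error")
})

test_that("coloc tidier carries the permutation summary", {
  mask <- ellipse_mask(20, 15, 0.25)
  d <- gen_coloc_dataset(0.5, 0.5, mask, n_cells = 1, n_seeds = 40, seed = 9)
  res <- randomized_null(d[d$channel == "seed", ],
                         d[d$channel == "antibody", ], mask, n_perm = 120,
                         seed = 10)
  td <- tidy(res)
  expect_named(td, c("observed", "null_mean", "null_sd", "p.value",
                     "n_perm", "radius_um"))
  expect_equal(td$n_perm, 120)
})
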