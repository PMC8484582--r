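# Shared fixtures and independent oracles.

default_rod <- rod_params()  # 5 um x 12 nm, water
kB <- 1.380649e-23

rot_diffusion <- function(rod, temperature_K = 293.15)
  kB * temperature_K / rod$gamma_J_s

# Brute-force circular range: smallest arc containing all angles, found by
# trying every sample as the arc's start. Independent of the sorted-gap
# implementation in the package.
brute_circular_range <- function(phi_rad) {
  w <- ((phi_rad + pi) %% (2 * pi)) - pi
  if (length(w) < 2) return(0)
  arc <- sapply(w, function(s) max((w - s) %% (2 * pi)))
  min(arc, 2 * pi)
}

# Stationary sampler at a dimensionless step c = a*dt (uniform Euler accuracy
# across kappa); for kappa = 0 the scheme is exact at any step, so sampling
# uses one long-jump step per retained value.
draw_stationary <- function(rod, kappa, n, seed, c_step = 0.02,
                            n_relax_lag = 5) {
  D <- rot_diffusion(rod)
  if (kappa == 0) {
    dt <- 40 / D  # free diffusion: variance 80 rad^2 per step, fully mixed
    return(sample_stationary(rod, 0, n, lag_s = dt, seed = seed, dt_s = dt,
                             burn_in_s = dt))
  }
  a <- kappa * D
  dt <- c_step / a
  sample_stationary(rod, kappa_to_velocity(rod, kappa), n,
                    lag_s = n_relax_lag / a, seed = seed, dt_s = dt,
                    burn_in_s = 20 / a)
}

# Two-sided KS distance between samples and the stationary law.
ks_vs_stationary <- function(samples, kappa) {
  x <- sort(windsock::wrap_angle(samples))
  Fx <- stationary_cdf(x, kappa)
  n <- length(x)
  max(abs(Fx - seq_len(n) / n), abs(Fx - (seq_len(n) - 1) / n))
}

# Minimal hand-built calibration object (documented structure) for unit
# tests of the inversion logic without simulation cost.
mock_calibration <- function(grid, mu, sd, n_pool = 400, seed = 99) {
  set.seed(seed)
  rods <- dplyr::bind_rows(lapply(seq_along(grid), function(i)
    tibble::tibble(shear_dyn_cm2 = grid[i], rod = seq_len(n_pool),
                   phi_deg = pmin(360, pmax(0, rnorm(n_pool, mu[i], sd[i]))))))
  curve <- rods |>
    dplyr::group_by(shear_dyn_cm2) |>
    dplyr::summarise(phi_mean_deg = mean(phi_deg), phi_sd_deg = sd(phi_deg),
                     ci_half_deg = 1.96 * sd(phi_deg) / sqrt(dplyr::n()),
                     n_rods = dplyr::n(), .groups = "drop")
  structure(list(curve = curve, rods = rods,
                 params = list(velocity_model = "near_wall", seed = seed)),
            class = "windsock_calibration")
}
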