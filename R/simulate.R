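# Drift rate a = (1/2) alpha mu U l^2 / gamma (1/s, signed with U) and
# effective rotational diffusion coefficient under a noise convention.
.rotor_rates <- function(rod, u_m_s, temperature_K, noise_convention,
                         viscosity_Pa_s = NULL) {
  mu <- viscosity_Pa_s %||% rod$viscosity_Pa_s
  l <- rod$length_um * 1e-6
  a <- 0.5 * rod$alpha * mu * u_m_s * l^2 / rod$gamma_J_s
  D0 <- .kB * temperature_K / rod$gamma_J_s
  D <- switch(noise_convention, fdt = D0, as_printed = D0 / 2)
  list(a = a, D = D)
}

.default_dt <- function(a, dt_cap = 1e-3) {
  if (abs(a) > 0) min(0.1 / abs(a), dt_cap) else dt_cap
}

.check_dt <- function(dt_s, a) {
  if (dt_s <= 0)
    abort("`dt_s` must be positive.", class = "windsock_domain_error")
  if (abs(a) > 0 && dt_s > 0.5 / abs(a))
    abort(sprintf(paste0("Time step %.3g s exceeds the stability bound ",
                         "0.5*gamma/(0.5*alpha*mu*|U|*l^2) = %.3g s; ",
                         "use dt_s <= %.3g s."),
                  dt_s, 0.5 / abs(a), 0.1 / abs(a)),
          class = "windsock_unstable_step")
}

#' Simulate the azimuth of a tethered rod in flow
#'
#' Euler--Maruyama integration of the overdamped Langevin equation
#' \deqn{\gamma \, d\phi/dt = -\tfrac12 \alpha \mu U l^2 \sin\phi + R(t),}
#' i.e. flow-induced restoring torque plus thermal noise. Under the default
#' `"fdt"` convention the noise satisfies the fluctuation--dissipation
#' relation \eqn{\mathrm{Var}(R) = 2 k_B T \gamma / \Delta t}, which makes the
#' stationary law Boltzmann (von Mises with [vonmises_kappa()]).
#' `"as_printed"` halves the noise variance
#' (\eqn{\mathrm{Var}(R) = k_B T \gamma / \Delta t}), reproducing a
#' literal reading of the model's stated noise density; it equilibrates to
#' temperature T/2.
#'
#' The integration step defaults to
#' `min(0.1 * gamma / (0.5 alpha mu |U| l^2), 1 ms)` and the function refuses
#' steps beyond half the deterministic relaxation time.
#'
#' @param rod A [rod_params()] object.
#' @param u_m_s Flow speed at the rod, m/s (signed; negative reverses the
#'   flow and moves the stationary mode from 0 to pi).
#' @param duration_s Trajectory length, s.
#' @param seed Integer RNG seed (required: trajectories are reproducible
#'   bit-for-bit from `(seed, parameters)`).
#' @param phi0_rad Initial azimuth, radians (unwrapped).
#' @param temperature_K Temperature, K.
#' @param dt_s Integration step, s (default as above).
#' @param record_dt_s Interval between stored samples, s; defaults to `dt_s`.
#'   Internally rounded to a whole number of steps.
#' @param noise_convention `"fdt"` (default) or `"as_printed"`.
#' @param viscosity_Pa_s Optional viscosity override, Pa s.
#' @return A tibble of class `windsock_trajectory` with columns `time_s` and
#'   `phi_rad` (unwrapped); simulation parameters are stored in
#'   `attr(, "params")`.
#' @examples
#' rod <- rod_params()
#' traj <- simulate_trajectory(rod, u_m_s = 0, duration_s = 10, seed = 1,
#'                             record_dt_s = 0.1)
#' @export
simulate_trajectory <- function(rod, u_m_s, duration_s, seed,
                                phi0_rad = 0, temperature_K = 293.15,
                                dt_s = NULL, record_dt_s = NULL,
                                noise_convention = c("fdt", "as_printed"),
                                viscosity_Pa_s = NULL) {
  stopifnot(inherits(rod, "rod_params"))
  noise_convention <- match.arg(noise_convention)
  if (duration_s <= 0)
    abort("`duration_s` must be positive.", class = "windsock_domain_error")
  rates <- .rotor_rates(rod, u_m_s, temperature_K, noise_convention,
                        viscosity_Pa_s)
  dt_s <- dt_s %||% .default_dt(rates$a)
  .check_dt(dt_s, rates$a)
  record_dt_s <- record_dt_s %||% dt_s
  record_every <- max(1L, as.integer(round(record_dt_s / dt_s)))
  n_steps <- as.integer(ceiling(duration_s / dt_s))
  # pad so the last recorded sample reaches `duration_s`
  n_steps <- as.integer(ceiling(n_steps / record_every) * record_every)
  set.seed(seed)
  phi <- bd_rotor(phi0_rad, n_steps, dt_s, rates$a, rates$D, record_every)
  out <- tibble(time_s = seq(0, by = dt_s * record_every,
                             length.out = length(phi)),
                phi_rad = phi)
  attr(out, "params") <- list(
    model = "tethered_rod_langevin", rod = unclass(rod), u_m_s = u_m_s,
    temperature_K = temperature_K, dt_s = dt_s,
    record_dt_s = dt_s * record_every, phi0_rad = phi0_rad, seed = seed,
    noise_convention = noise_convention,
    kappa = vonmises_kappa(rod, u_m_s, temperature_K, viscosity_Pa_s))
  class(out) <- c("windsock_trajectory", class(out))
  out
}

#' Decorrelated stationary samples of the rod azimuth
#'
#' Runs the same dynamics as [simulate_trajectory()] but stores only every
#' `lag_s` seconds after a burn-in, for equilibrium-statistics work where the
#' full path is not needed.
#'
#' @inheritParams simulate_trajectory
#' @param n_samples Number of samples to return.
#' @param lag_s Time between consecutive retained samples, s.
#' @param burn_in_s Discarded initial stretch, s.
#' @return Numeric vector of unwrapped azimuth samples.
#' @export
sample_stationary <- function(rod, u_m_s, n_samples, lag_s, seed,
                              burn_in_s = 10 * lag_s, phi0_rad = 0,
                              temperature_K = 293.15, dt_s = NULL,
                              noise_convention = c("fdt", "as_printed"),
                              viscosity_Pa_s = NULL) {
  stopifnot(inherits(rod, "rod_params"))
  noise_convention <- match.arg(noise_convention)
  rates <- .rotor_rates(rod, u_m_s, temperature_K, noise_convention,
                        viscosity_Pa_s)
  dt_s <- dt_s %||% .default_dt(rates$a, dt_cap = lag_s)
  .check_dt(dt_s, rates$a)
  lag <- max(1L, as.integer(round(lag_s / dt_s)))
  burn <- as.integer(ceiling(burn_in_s / dt_s))
  set.seed(seed)
  bd_rotor_thin(phi0_rad, burn, as.integer(n_samples), lag, dt_s,
                rates$a, rates$D)
}

#' Simulate a population of independently anchored rods
#'
#' Each rod starts from an azimuth drawn uniformly on \eqn{(-\pi, \pi]} and
#' evolves independently; per-rod seeds are derived deterministically from
#' the master seed.
#'
#' @inheritParams simulate_trajectory
#' @param n_rods Number of rods (>= 1).
#' @param record_dt_s Stored sampling interval, s.
#' @return A tibble with columns `rod`, `time_s`, `phi_rad`; per-rod initial
#'   angles and seeds are in `attr(, "params")`.
#' @export
sample_population <- function(n_rods, rod, u_m_s, duration_s, seed,
                              temperature_K = 293.15, dt_s = NULL,
                              record_dt_s = NULL,
                              noise_convention = c("fdt", "as_printed"),
                              viscosity_Pa_s = NULL) {
  if (n_rods < 1)
    abort("`n_rods` must be >= 1.", class = "windsock_domain_error")
  noise_convention <- match.arg(noise_convention)
  set.seed(seed)
  phi0 <- runif(n_rods, -pi, pi)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_rods)
  runs <- purrr::map(seq_len(n_rods), function(i) {
    tr <- simulate_trajectory(rod, u_m_s, duration_s, seed = sub_seeds[i],
                              phi0_rad = phi0[i],
                              temperature_K = temperature_K, dt_s = dt_s,
                              record_dt_s = record_dt_s,
                              noise_convention = noise_convention,
                              viscosity_Pa_s = viscosity_Pa_s)
    dplyr::mutate(as_tibble(tr), rod = i, .before = 1)
  })
  out <- dplyr::bind_rows(runs)
  attr(out, "params") <- list(
    n_rods = n_rods, rod = unclass(rod), u_m_s = u_m_s,
    duration_s = duration_s, seed = seed, phi0_rad = phi0,
    sub_seeds = sub_seeds, temperature_K = temperature_K,
    noise_convention = noise_convention)
  out
}

#' Two-angle Brownian dynamics on the hemisphere
#'
#' Optional extension tracking both the polar angle theta (from the z axis)
#' and the azimuth phi, with potential
#' \eqn{E(\theta, \phi) = -\tfrac12 \alpha \mu U l^2 \sin\theta \cos\phi}
#' whose phi-gradient at \eqn{\theta = \pi/2} reproduces the in-plane torque.
#' The wall constrains \eqn{\theta \le \pi/2} (reflecting boundary). At
#' moderate-to-high flow the polar angle stays near \eqn{\pi/2}, which is the
#' justification for the one-angle reduction used everywhere else.
#'
#' @inheritParams simulate_trajectory
#' @param theta0_rad,phi0_rad Initial angles, radians.
#' @return A tibble with columns `time_s`, `theta_rad`, `phi_rad`.
#' @export
simulate_spherical <- function(rod, u_m_s, duration_s, seed,
                               theta0_rad = pi / 3, phi0_rad = 0,
                               temperature_K = 293.15, dt_s = NULL,
                               record_dt_s = NULL,
                               noise_convention = c("fdt", "as_printed"),
                               viscosity_Pa_s = NULL) {
  stopifnot(inherits(rod, "rod_params"))
  noise_convention <- match.arg(noise_convention)
  if (theta0_rad <= 0 || theta0_rad > pi / 2)
    abort("`theta0_rad` must lie in (0, pi/2].", class = "windsock_domain_error")
  rates <- .rotor_rates(rod, u_m_s, temperature_K, noise_convention,
                        viscosity_Pa_s)
  b <- rates$a  # same rate constant drives both angles
  # the metric drift ~ D cot(theta) also bounds the step near the pole
  dt_s <- dt_s %||% min(.default_dt(b), 0.05 / rates$D)
  .check_dt(dt_s, b)
  record_dt_s <- record_dt_s %||% dt_s
  record_every <- max(1L, as.integer(round(record_dt_s / dt_s)))
  n_steps <- as.integer(ceiling(duration_s / dt_s))
  n_steps <- as.integer(ceiling(n_steps / record_every) * record_every)
  set.seed(seed)
  m <- bd_spherical(theta0_rad, phi0_rad, n_steps, dt_s, b, rates$D,
                    record_every)
  tibble(time_s = seq(0, by = dt_s * record_every, length.out = nrow(m)),
         theta_rad = m[, 1], phi_rad = m[, 2])
}

#' Wrap angles to the interval (-pi, pi]
#'
#' @param phi_rad Angles in radians.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(phi_rad) {
  w <- (phi_rad + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}
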