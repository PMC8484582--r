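#' Imaging protocol for the total-angle statistic
#'
#' The default (30 frames, one every 5 s) is the time-lapse protocol used to
#' read nanotube orientations from maximum time projections.
#'
#' @param n_frames Number of frames (>= 2).
#' @param interval_s Frame interval, s (> 0).
#' @return An object of class `sampling_protocol`.
#' @export
sampling_protocol <- function(n_frames = 30, interval_s = 5) {
  if (n_frames < 2)
    abort("`n_frames` must be >= 2.", class = "windsock_domain_error")
  if (interval_s <= 0)
    abort("`interval_s` must be positive.", class = "windsock_domain_error")
  structure(list(n_frames = as.integer(n_frames), interval_s = interval_s),
            class = "sampling_protocol")
}

#' @export
print.sampling_protocol <- function(x, ...) {
  cat(sprintf("<sampling_protocol> %d frames every %g s (duration %g s)\n",
              x$n_frames, x$interval_s, (x$n_frames - 1) * x$interval_s))
  invisible(x)
}

# Circular range of a set of angles: the smallest arc containing every
# wrapped angle, i.e. 2*pi minus the largest gap between consecutive sorted
# wrapped samples. Returns radians in [0, 2*pi].
.circular_range <- function(phi_rad) {
  w <- sort(wrap_angle(phi_rad))
  if (length(w) < 2) return(0)
  gaps <- c(diff(w), 2 * pi - (w[length(w)] - w[1]))
  2 * pi - max(gaps)
}

#' Total rotation angle of a rod over an imaging protocol
#'
#' The "windsock" statistic Phi: the trajectory is sampled at the protocol's
#' frame times and Phi is the angular extent of the sampled orientations ---
#' 360 degrees minus the largest empty arc between the wrapped samples
#' (capped at 360). This formalises reading the total range of angular motion
#' off a maximum time projection. Phi is a set statistic: it is invariant to
#' the time order of the frames and equivariant under global rotation.
#'
#' @param traj A trajectory tibble with columns `time_s` and an angle column;
#'   if a `rod` column is present, Phi is computed per rod.
#' @param protocol A [sampling_protocol()].
#' @param phi_col Name of the angle column (radians, unwrapped or wrapped).
#' @return For a single trajectory, Phi in degrees; with a `rod` column, a
#'   tibble with columns `rod` and `phi_deg`.
#' @examples
#' tr <- tibble::tibble(time_s = seq(0, 145, by = 5),
#'                      phi_rad = c(0, pi / 2, pi, 3 * pi / 2, rep(0, 26)))
#' total_angle(tr)  # 270 degrees
#' @export
total_angle <- function(traj, protocol = sampling_protocol(),
                        phi_col = "phi_rad") {
  stopifnot(inherits(protocol, "sampling_protocol"))
  if (!is.data.frame(traj) || !all(c("time_s", phi_col) %in% names(traj)))
    abort(sprintf("`traj` must contain columns `time_s` and `%s`.", phi_col),
          class = "windsock_domain_error")
  frame_t <- (seq_len(protocol$n_frames) - 1) * protocol$interval_s
  one <- function(d) {
    if (max(d$time_s) < frame_t[length(frame_t)] - 1e-9)
      abort(sprintf(paste0("Trajectory covers %.3g s but the protocol needs ",
                           "%.3g s."), max(d$time_s), frame_t[length(frame_t)]),
            class = "windsock_coverage_error")
    ph <- approx(d$time_s, d[[phi_col]], xout = frame_t, ties = "ordered")$y
    .circular_range(ph) * 180 / pi
  }
  if ("rod" %in% names(traj)) {
    traj |>
      dplyr::group_by(.data$rod) |>
      dplyr::group_modify(~ tibble(phi_deg = one(.x))) |>
      dplyr::ungroup()
  } else {
    one(traj)
  }
}

#' Calibration curve: mean total angle versus wall shear stress
#'
#' For each stress on the grid, converts shear stress to the drive velocity
#' felt by the rod ([shear_to_velocity()]), simulates a population of
#' independently anchored rods over the imaging protocol, computes per-rod
#' total angles, and summarises the population (mean, sd, t-based 95% CI over
#' rods). Per-rod Phi values are retained for inversion by
#' [estimate_shear()].
#'
#' @param shear_grid_dyn_cm2 Increasing grid of non-negative wall shear
#'   stresses, dyn/cm^2.
#' @param n_rods Rods simulated per stress.
#' @param rod A [rod_params()] object.
#' @param geom A [channel_geometry()]; used by the `"mean"` velocity model.
#' @param protocol A [sampling_protocol()].
#' @param seed Master RNG seed.
#' @param viscosity_P Perfusate viscosity, poise.
#' @param velocity_model,wall_offset_nm See [shear_to_velocity()].
#' @param temperature_K Temperature, K.
#' @param dt_s Optional integration step override, s.
#' @param length_dist Optional function `n -> lengths (um)` drawing per-rod
#'   lengths, as a rod-heterogeneity sensitivity knob; default fixed length.
#' @param equilibrate_s Flow-on equilibration time simulated before the
#'   acquisition window, s. Imaging starts only once the flow (and hence the
#'   angular distribution) is established; without this burn-in every rod
#'   would sweep from its uniform no-flow angle to the flow-aligned mode
#'   inside the protocol window, inflating Phi at high stress. Rounded up to
#'   a whole number of frame intervals.
#' @param conf_level Confidence level for the per-stress CI.
#' @return An object of class `windsock_calibration`: list with `curve`
#'   (per-stress summary tibble), `rods` (per-rod Phi tibble) and `params`.
#' @export
build_calibration <- function(shear_grid_dyn_cm2, n_rods = 15,
                              rod = rod_params(),
                              geom = ibidi_channel("VI_0.4"),
                              protocol = sampling_protocol(), seed = 1,
                              viscosity_P = 0.01,
                              velocity_model = c("near_wall", "mean"),
                              wall_offset_nm = 25, temperature_K = 293.15,
                              dt_s = NULL, length_dist = NULL,
                              equilibrate_s = 60, conf_level = 0.95) {
  velocity_model <- match.arg(velocity_model)
  if (any(shear_grid_dyn_cm2 < 0) || is.unsorted(shear_grid_dyn_cm2, strictly = TRUE))
    abort("`shear_grid_dyn_cm2` must be non-negative and strictly increasing.",
          class = "windsock_domain_error")
  burn <- ceiling(equilibrate_s / protocol$interval_s) * protocol$interval_s
  duration <- burn + (protocol$n_frames - 1) * protocol$interval_s
  set.seed(seed)
  stress_seeds <- sample.int(.Machine$integer.max - 1L,
                             length(shear_grid_dyn_cm2))
  per_stress <- purrr::map2(shear_grid_dyn_cm2, stress_seeds, function(tau, s) {
    u <- shear_to_velocity(geom, tau, viscosity_P, velocity_model,
                           wall_offset_nm)
    if (is.null(length_dist)) {
      pop <- sample_population(n_rods, rod, u, duration, seed = s,
                               temperature_K = temperature_K, dt_s = dt_s,
                               record_dt_s = protocol$interval_s)
      pop <- dplyr::filter(pop, .data$time_s >= burn - 1e-9) |>
        dplyr::mutate(time_s = .data$time_s - burn)
      phi <- total_angle(pop, protocol)$phi_deg
    } else {
      set.seed(s)
      lens <- length_dist(n_rods)
      sub <- sample.int(.Machine$integer.max - 1L, n_rods)
      phi0 <- runif(n_rods, -pi, pi)
      phi <- vapply(seq_len(n_rods), function(i) {
        ri <- rod_params(lens[i], rod$diameter_nm, rod$persistence_length_um,
                         rod$viscosity_Pa_s)
        tr <- simulate_trajectory(ri, u, duration, seed = sub[i],
                                  phi0_rad = phi0[i],
                                  temperature_K = temperature_K, dt_s = dt_s,
                                  record_dt_s = protocol$interval_s)
        tr <- dplyr::mutate(dplyr::filter(tr, .data$time_s >= burn - 1e-9),
                            time_s = .data$time_s - burn)
        total_angle(tr, protocol)
      }, numeric(1))
    }
    tibble(shear_dyn_cm2 = tau, rod = seq_along(phi), phi_deg = phi)
  })
  rods <- dplyr::bind_rows(per_stress)
  tcrit <- qt(1 - (1 - conf_level) / 2, df = n_rods - 1)
  curve <- rods |>
    dplyr::group_by(.data$shear_dyn_cm2) |>
    dplyr::summarise(phi_mean_deg = mean(.data$phi_deg),
                     phi_sd_deg = sd(.data$phi_deg),
                     ci_half_deg = tcrit * sd(.data$phi_deg) / sqrt(dplyr::n()),
                     n_rods = dplyr::n(), .groups = "drop")
  structure(list(curve = curve, rods = rods,
                 params = list(rod = unclass(rod), geom = unclass(geom),
                               protocol = unclass(protocol), seed = seed,
                               viscosity_P = viscosity_P,
                               velocity_model = velocity_model,
                               wall_offset_nm = wall_offset_nm,
                               temperature_K = temperature_K,
                               equilibrate_s = burn,
                               conf_level = conf_level)),
            class = "windsock_calibration")
}

#' @export
print.windsock_calibration <- function(x, ...) {
  cat(sprintf("<windsock_calibration> %d stresses, %d rods each (%s drive)\n",
              nrow(x$curve), x$curve$n_rods[1], x$params$velocity_model))
  print(x$curve)
  invisible(x)
}

# Non-increasing isotonic fit of y over increasing x.
.iso_dec <- function(x, y) -isoreg(x, -y)$yf

# Invert a non-increasing step-ish curve: largest x with f(x) >= target,
# by linear interpolation on strictly decreasing segments.
.invert_dec <- function(x, y_dec, target) {
  if (target > max(y_dec)) return(NA_real_)   # above curve: saturated
  if (target < min(y_dec)) return(NA_real_)   # below curve: out of range
  # walk from the left; interpolate within the first bracketing segment
  for (i in seq_len(length(x) - 1)) {
    y1 <- y_dec[i]; y2 <- y_dec[i + 1]
    if (target <= y1 && target >= y2) {
      if (y1 == y2) return((x[i] + x[i + 1]) / 2)
      return(x[i] + (y1 - target) / (y1 - y2) * (x[i + 1] - x[i]))
    }
  }
  x[length(x)]
}

#' Estimate wall shear stress from an observed mean total angle
#'
#' Inverts a calibration curve. The point estimate interpolates the
#' isotonic-smoothed (non-increasing) mean curve. The confidence interval is
#' a Neyman belt built by parametric bootstrap: at each calibration stress,
#' the sampling distribution of a mean over `n_observed` rods is estimated by
#' resampling the calibration's per-rod Phi values; the CI is the set of
#' stresses whose belt contains the observation.
#'
#' If the observation exceeds the curve's maximum (the sensor's flat
#' low-stress plateau), the estimate saturates at the lowest calibrated
#' stress and the result is flagged `saturated`. An observation below the
#' curve's minimum raises an extrapolation error (beyond dynamic range).
#'
#' @param phi_mean_deg Observed mean total angle over `n_observed` rods,
#'   degrees.
#' @param n_observed Number of rods averaged in the observation.
#' @param curve A [build_calibration()] result (must retain per-rod values).
#' @param conf_level Confidence level.
#' @param n_boot Bootstrap resamples per calibration stress.
#' @param seed RNG seed for the bootstrap.
#' @return An object of class `windsock_shear_estimate`: list with
#'   `tau_hat`, `ci_lower`, `ci_upper` (dyn/cm^2), `saturated`, `phi_obs_deg`,
#'   `n_observed`, `conf_level`.
#' @export
estimate_shear <- function(phi_mean_deg, n_observed, curve,
                           conf_level = 0.95, n_boot = 1000, seed = 1) {
  stopifnot(inherits(curve, "windsock_calibration"))
  grid <- curve$curve$shear_dyn_cm2
  mu <- .iso_dec(grid, curve$curve$phi_mean_deg)
  alpha <- 1 - conf_level
  set.seed(seed)
  qs <- purrr::map(grid, function(tau) {
    pool <- curve$rods$phi_deg[curve$rods$shear_dyn_cm2 == tau]
    means <- vapply(seq_len(n_boot), function(i)
      mean(sample(pool, n_observed, replace = TRUE)), numeric(1))
    quantile(means, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  })
  q_lo <- .iso_dec(grid, vapply(qs, `[`, numeric(1), 1))
  q_hi <- .iso_dec(grid, vapply(qs, `[`, numeric(1), 2))

  saturated <- phi_mean_deg >= max(mu)
  if (phi_mean_deg < min(q_lo))
    abort(sprintf(paste0("Observed mean angle %.1f deg lies below the ",
                         "calibration range (min %.1f deg): stress beyond ",
                         "the sensor's calibrated dynamic range."),
                  phi_mean_deg, min(q_lo)),
          class = "windsock_extrapolation_error")
  tau_hat <- if (saturated) grid[1] else .invert_dec(grid, mu, phi_mean_deg)
  # belt: obs <= q_hi(tau) for tau <= upper limit; obs >= q_lo(tau) for
  # tau >= lower limit (both curves non-increasing in tau)
  ci_upper <- if (phi_mean_deg < min(q_hi)) grid[length(grid)] else
    .invert_dec(grid, q_hi, phi_mean_deg)
  ci_lower <- if (phi_mean_deg >= max(q_lo)) grid[1] else
    .invert_dec(grid, q_lo, phi_mean_deg)
  if (saturated)
    warn("Observed angle is on the flat low-stress plateau; estimate saturated at the lowest calibrated stress.",
         class = "windsock_saturation_warning")
  structure(list(tau_hat = tau_hat, ci_lower = ci_lower, ci_upper = ci_upper,
                 saturated = saturated, phi_obs_deg = phi_mean_deg,
                 n_observed = n_observed, conf_level = conf_level),
            class = "windsock_shear_estimate")
}

#' @export
print.windsock_shear_estimate <- function(x, ...) {
  cat(sprintf(paste0("<windsock_shear_estimate> tau = %.3g dyn/cm^2 ",
                     "[%.3g, %.3g] (%d%% CI)%s\n"),
              x$tau_hat, x$ci_lower, x$ci_upper, round(100 * x$conf_level),
              if (x$saturated) " [saturated]" else ""))
  invisible(x)
}
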