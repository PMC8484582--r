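#' Study parameter presets
#'
#' The constants used throughout the reported experiments, collected in one
#' version-stamped list: filament persistence length, the two flow-channel
#' geometries, the imaging protocol, the shear-stress grids of the
#' glass/cell flow series, the surface-persistence decay parameters for
#' seeds and seeded nanotubes, the SpyTag attachment scenario, and the
#' cohort sizes.
#'
#' @return Named list of presets.
#' @export
windsock_presets <- function() {
  list(
    version = "0.1.0",
    persistence_length_um = 8.7,
    channels = list(VI_0.4 = list(height_mm = 0.4, width_mm = 3.8, length_mm = 17),
                    VI_0.5 = list(height_mm = 0.54, width_mm = 3.8, length_mm = 17)),
    protocol = list(n_frames = 30, interval_s = 5),
    shear_grid_confocal = c(0, 0.05, 0.2, 1),
    shear_grid_projection = c(0, 0.1, 0.4, 1.2, 1.6),
    shear_grid_phi = c(0.05, 0.1, 0.4, 1.2, 1.6, 2.0),
    decay = list(seeds = list(a = 1.0, b_per_h = 3.3),
                 nanotubes = list(a = 1.0, b_per_h = 0.52)),
    spytag = list(k_on_M_s = 1400, conc_M = 64e-12, n_receptors = 1e4),
    coloc = list(observed_pct = 76, null_pct = 20, n_cells = 12),
    n_rods_per_stress = 15,
    n_cells_decay = 6
  )
}

#' Synthetic azimuth dataset: trajectories plus noisy frame readings
#'
#' Simulates a population of anchored rods at a given wall shear stress and
#' derives the per-frame angle readings an imaging pipeline would produce,
#' adding wrapped-Gaussian measurement noise to the true sampled angles.
#' Ground truth is kept alongside the observations.
#'
#' @param shear_dyn_cm2 Wall shear stress, dyn/cm^2.
#' @param n_rods Number of rods.
#' @param rod A [rod_params()].
#' @param geom A [channel_geometry()].
#' @param protocol A [sampling_protocol()].
#' @param noise_sd_deg Angular measurement noise sd, degrees.
#' @param equilibrate_s Flow-on equilibration before acquisition, s (see
#'   [build_calibration()]).
#' @param seed Master seed.
#' @param velocity_model,wall_offset_nm,viscosity_P See [shear_to_velocity()].
#' @param temperature_K Temperature, K.
#' @return List with `trajectories` (long tibble `rod`, `time_s`,
#'   `phi_rad`), `frames` (tibble `rod`, `frame`, `time_s`, `phi_true_rad`,
#'   `phi_obs_rad`) and `manifest` (all generation parameters).
#' @export
gen_angle_dataset <- function(shear_dyn_cm2, n_rods = 15,
                              rod = rod_params(),
                              geom = ibidi_channel("VI_0.4"),
                              protocol = sampling_protocol(),
                              noise_sd_deg = 3, equilibrate_s = 60, seed = 1,
                              velocity_model = c("near_wall", "mean"),
                              wall_offset_nm = 25, viscosity_P = 0.01,
                              temperature_K = 293.15) {
  velocity_model <- match.arg(velocity_model)
  u <- shear_to_velocity(geom, shear_dyn_cm2, viscosity_P, velocity_model,
                         wall_offset_nm)
  burn <- ceiling(equilibrate_s / protocol$interval_s) * protocol$interval_s
  duration <- burn + (protocol$n_frames - 1) * protocol$interval_s
  pop <- sample_population(n_rods, rod, u, duration, seed = seed,
                           temperature_K = temperature_K,
                           record_dt_s = protocol$interval_s)
  pop <- dplyr::filter(pop, .data$time_s >= burn - 1e-9) |>
    dplyr::mutate(time_s = .data$time_s - burn)
  frame_t <- (seq_len(protocol$n_frames) - 1) * protocol$interval_s
  frames <- pop |>
    dplyr::group_by(.data$rod) |>
    dplyr::group_modify(function(d, g) {
      tibble(frame = seq_along(frame_t), time_s = frame_t,
             phi_true_rad = approx(d$time_s, d$phi_rad, xout = frame_t,
                                   ties = "ordered")$y)
    }) |>
    dplyr::ungroup()
  set.seed(seed + 1L)
  frames$phi_obs_rad <- wrap_angle(frames$phi_true_rad +
                                     rnorm(nrow(frames), 0, noise_sd_deg * pi / 180))
  manifest <- list(generator = "gen_angle_dataset",
                   shear_dyn_cm2 = shear_dyn_cm2, n_rods = n_rods,
                   rod = unclass(rod), geom = unclass(geom),
                   protocol = unclass(protocol), noise_sd_deg = noise_sd_deg,
                   equilibrate_s = burn,
                   seed = seed, velocity_model = velocity_model,
                   wall_offset_nm = wall_offset_nm,
                   viscosity_P = viscosity_P, temperature_K = temperature_K,
                   version = windsock_presets()$version)
  list(trajectories = pop, frames = frames, manifest = manifest)
}

#' Synthetic surface-persistence decay series
#'
#' Per-cell fractions of structures remaining on the cell surface:
#' \eqn{y = a e^{-b t}} plus Gaussian noise, clipped at zero and renormalised
#' so each cell's t = 0 fraction is exactly 1 (as persistence counts are
#' normalised to their initial value).
#'
#' @param b_per_h Decay rate, 1/h.
#' @param a Amplitude.
#' @param times_h Sampling times, h; must include 0. Defaults to the
#'   seed-series design (every 10 min over 70 min).
#' @param noise_sd Additive noise sd on the fraction scale.
#' @param n_cells Number of cells.
#' @param seed RNG seed.
#' @return Tibble `cell`, `time_h`, `fraction`, with the generation
#'   parameters in `attr(, "manifest")`.
#' @export
gen_decay_dataset <- function(b_per_h, a = 1,
                              times_h = seq(0, 70, by = 10) / 60,
                              noise_sd = 0.02, n_cells = 6, seed = 1) {
  if (b_per_h < 0)
    abort("`b_per_h` must be non-negative.", class = "windsock_domain_error")
  if (!any(abs(times_h) < 1e-12))
    abort("`times_h` must include 0 (the normalisation point).",
          class = "windsock_domain_error")
  set.seed(seed)
  out <- purrr::map(seq_len(n_cells), function(cl) {
    y <- a * exp(-b_per_h * times_h) + rnorm(length(times_h), 0, noise_sd)
    y <- pmax(y, 0)
    y <- y / y[which.min(abs(times_h))]
    tibble(cell = cl, time_h = times_h, fraction = y)
  }) |> dplyr::bind_rows()
  attr(out, "manifest") <- list(generator = "gen_decay_dataset", a = a,
                                b_per_h = b_per_h, times_h = times_h,
                                noise_sd = noise_sd, n_cells = n_cells,
                                seed = seed,
                                version = windsock_presets()$version)
  out
}

#' Synthetic colocalization point patterns
#'
#' Per cell: an antibody pattern drawn as a homogeneous Poisson process of
#' intensity `lambda_per_um2` inside the mask, and `n_seeds` seed points of
#' which a fraction `true_fraction` are planted within `radius_um` of a
#' random antibody (truly colocalized) while the rest are uniform in the
#' mask.
#'
#' @param true_fraction Fraction of seeds truly colocalized, in \[0, 1\].
#' @param lambda_per_um2 Antibody intensity, points/um^2.
#' @param mask A `windsock_mask`.
#' @param n_cells Number of cells.
#' @param n_seeds Seed points per cell.
#' @param radius_um Planting radius for the colocalized seeds, um.
#' @param seed RNG seed.
#' @return Tibble `cell`, `channel` ("seed"/"antibody"), `x_um`, `y_um`,
#'   `colocalized` (ground truth, `NA` for antibodies); manifest in
#'   `attr(, "manifest")`.
#' @export
gen_coloc_dataset <- function(true_fraction, lambda_per_um2,
                              mask = ellipse_mask(), n_cells = 12,
                              n_seeds = 150, radius_um = 0.5, seed = 1) {
  if (true_fraction < 0 || true_fraction > 1)
    abort("`true_fraction` must be in [0, 1].", class = "windsock_domain_error")
  area <- mask_area(mask)
  if (lambda_per_um2 < 0 || area <= 0)
    abort("Inconsistent mask/intensity.", class = "windsock_domain_error")
  set.seed(seed)
  out <- purrr::map(seq_len(n_cells), function(cl) {
    n_ab <- rpois(1, lambda_per_um2 * area)
    ab <- sample_in_mask(n_ab, mask)
    is_coloc <- runif(n_seeds) < true_fraction & n_ab > 0
    sd_pts <- sample_in_mask(n_seeds, mask)
    if (any(is_coloc)) {
      for (i in which(is_coloc)) {
        repeat {
          j <- sample.int(n_ab, 1)
          rr <- radius_um * sqrt(runif(1)); th <- runif(1, 0, 2 * pi)
          cand <- tibble(x_um = ab$x_um[j] + rr * cos(th),
                         y_um = ab$y_um[j] + rr * sin(th))
          if (in_mask(cand, mask)) break
        }
        sd_pts$x_um[i] <- cand$x_um; sd_pts$y_um[i] <- cand$y_um
      }
    }
    dplyr::bind_rows(
      tibble(cell = cl, channel = "antibody", x_um = ab$x_um, y_um = ab$y_um,
             colocalized = NA),
      tibble(cell = cl, channel = "seed", x_um = sd_pts$x_um,
             y_um = sd_pts$y_um, colocalized = is_coloc))
  }) |> dplyr::bind_rows()
  attr(out, "manifest") <- list(generator = "gen_coloc_dataset",
                                true_fraction = true_fraction,
                                lambda_per_um2 = lambda_per_um2,
                                mask_area_um2 = area,
                                pixel_um = mask$pixel_um, n_cells = n_cells,
                                n_seeds = n_seeds, radius_um = radius_um,
                                seed = seed,
                                version = windsock_presets()$version)
  out
}
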