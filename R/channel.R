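#' Rectangular flow-channel geometry
#'
#' Defines the cross-section of a rectangular microchannel in the wide-channel
#' orientation (width >= height). Dimensions are given in millimetres, the
#' unit vendors print. Named commercial channels are available through
#' [ibidi_channel()].
#'
#' @param height_mm Channel height H (the small dimension, across which the
#'   parabolic profile develops), mm.
#' @param width_mm Channel width W, mm. Must satisfy `width_mm >= height_mm`.
#' @param length_mm Channel length, mm (informational; not used in the
#'   fully-developed-flow formulas).
#' @param name Optional label carried through to outputs.
#' @return An object of class `channel_geometry`.
#' @examples
#' channel_geometry(height_mm = 0.4, width_mm = 3.8, length_mm = 17)
#' @export
channel_geometry <- function(height_mm, width_mm, length_mm = NA_real_,
                             name = NULL) {
  if (!is.numeric(height_mm) || length(height_mm) != 1L || height_mm <= 0)
    abort("`height_mm` must be a single positive number.",
          class = "windsock_invalid_geometry")
  if (!is.numeric(width_mm) || length(width_mm) != 1L || width_mm <= 0)
    abort("`width_mm` must be a single positive number.",
          class = "windsock_invalid_geometry")
  if (width_mm < height_mm)
    abort("Wide-channel orientation required: `width_mm` must be >= `height_mm`.",
          class = "windsock_invalid_geometry")
  structure(
    list(height_mm = height_mm, width_mm = width_mm, length_mm = length_mm,
         name = name %||% "custom"),
    class = "channel_geometry"
  )
}

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("<channel_geometry> %s: H = %g mm, W = %g mm, L = %g mm\n",
              x$name, x$height_mm, x$width_mm, x$length_mm))
  invisible(x)
}

#' Named channel presets
#'
#' Looks up a commercial channel in the shipped YAML registry
#' (`inst/extdata/channels.yml`). The two Ibidi mu-slide VI channels used for
#' glass- and cell-anchored nanotube flow experiments are included.
#'
#' @param name Preset key, e.g. `"VI_0.4"` or `"VI_0.5"` (an `"ibidi_"`
#'   prefix is accepted and ignored).
#' @return A [channel_geometry()] object.
#' @examples
#' ibidi_channel("VI_0.4")
#' @export
ibidi_channel <- function(name = c("VI_0.4", "VI_0.5")) {
  reg <- yaml::read_yaml(system.file("extdata", "channels.yml",
                                     package = "windsock", mustWork = TRUE))
  key <- sub("^ibidi_", "", name[1])
  key <- paste0("ibidi_", key)
  if (!key %in% names(reg))
    abort(sprintf("Unknown channel preset '%s'. Available: %s.", name[1],
                  paste(names(reg), collapse = ", ")),
          class = "windsock_invalid_geometry")
  p <- reg[[key]]
  channel_geometry(p$height_mm, p$width_mm, p$length_mm, name = key)
}

#' Mean flow velocity in a rectangular channel
#'
#' Converts a volumetric flow rate Q to the cross-section mean velocity
#' U = Q / (H W).
#'
#' @param geom A [channel_geometry()].
#' @param flow_ml_min Volumetric flow rate, mL/min. May be a vector.
#' @return Mean velocity in cm/s.
#' @examples
#' mean_velocity(ibidi_channel("VI_0.4"), 0.18)  # ~0.197 cm/s
#' @export
mean_velocity <- function(geom, flow_ml_min) {
  stopifnot(inherits(geom, "channel_geometry"))
  if (any(flow_ml_min < 0))
    abort("`flow_ml_min` must be non-negative.", class = "windsock_invalid_flow")
  q_cm3_s <- flow_ml_min / 60
  area_cm2 <- (geom$height_mm / 10) * (geom$width_mm / 10)
  q_cm3_s / area_cm2
}

# Odd-mode series pieces of the exact rectangular-duct Poiseuille solution.
# h, w in cm. Returns the flow-rate correction factor Fp (so that
# Q = h^3 w G Fp / (12 mu)) and the bottom-wall centreline shear sum S (so
# that tau = 4 h G S / pi^2), with G the pressure gradient. The shear sum
# sum_{n odd} (1 - sech(n pi w / 2h))/n^2 is evaluated via the identity
# sum_{n odd} 1/n^2 = pi^2/8, leaving only the exponentially decaying sech
# tail to truncate.
.duct_series <- function(h, w, modes, tol) {
  n <- seq(1, by = 2, length.out = modes)
  x <- n * pi * w / (2 * h)
  fp_terms <- 192 * h / (pi^5 * n^5 * w) * tanh(x)
  Fp <- 1 - sum(fp_terms)
  sech_terms <- (1 / cosh(x)) / n^2
  S <- pi^2 / 8 - sum(sech_terms)
  # convergence: the last retained term must be negligible in both sums
  rel <- max(fp_terms[modes] / max(Fp, .Machine$double.eps),
             sech_terms[modes] / S)
  if (rel > tol)
    abort(sprintf(paste0("Duct series not converged: last-mode relative ",
                         "contribution %.2e > tol %.2e. Increase `modes`."),
                  rel, tol),
          class = "windsock_series_tolerance")
  list(Fp = Fp, S = S)
}

#' Wall shear stress in a rectangular channel
#'
#' Shear stress at the centre of the bottom wall for fully developed laminar
#' flow of a Newtonian fluid, from the exact Fourier-series solution of
#' Poiseuille flow in a rectangular duct. As the aspect ratio W/H grows the
#' result converges to the parallel-plate formula
#' \eqn{\tau = 6 \mu Q / (W H^2)}, which is available as `method = "plates"`.
#'
#' @param geom A [channel_geometry()].
#' @param flow_ml_min Volumetric flow rate, mL/min (vectorised).
#' @param viscosity_P Dynamic viscosity in poise (dyn s/cm^2). Water is about
#'   0.01 P at 20 degC and 0.0069 P at 37 degC.
#' @param method `"series"` (exact duct solution, default) or `"plates"`
#'   (infinite-parallel-plate approximation).
#' @param modes Number of odd Fourier modes retained in the series.
#' @param tol Relative tolerance demanded of the truncated series.
#' @return Wall shear stress in dyn/cm^2.
#' @examples
#' # the flow used to stretch nanotubes on cells: 0.18 mL/min in a VI 0.4 slide
#' wall_shear_stress(ibidi_channel("VI_0.4"), 0.18, viscosity_P = 0.01)
#' @export
wall_shear_stress <- function(geom, flow_ml_min, viscosity_P = 0.01,
                              method = c("series", "plates"),
                              modes = 101, tol = 1e-8) {
  stopifnot(inherits(geom, "channel_geometry"))
  method <- match.arg(method)
  if (any(flow_ml_min < 0))
    abort("`flow_ml_min` must be non-negative.", class = "windsock_invalid_flow")
  if (viscosity_P <= 0)
    abort("`viscosity_P` must be positive.", class = "windsock_invalid_flow")
  h <- geom$height_mm / 10  # cm
  w <- geom$width_mm / 10
  q <- flow_ml_min / 60     # cm^3/s
  if (method == "plates")
    return(6 * viscosity_P * q / (w * h^2))
  ser <- .duct_series(h, w, modes, tol)
  G <- 12 * viscosity_P * q / (h^3 * w * ser$Fp)   # pressure gradient, dyn/cm^3
  4 * h * G * ser$S / pi^2
}

#' Flow rate producing a target wall shear stress
#'
#' Inverse of [wall_shear_stress()], exploiting the exact linearity of shear
#' stress in flow rate.
#'
#' @inheritParams wall_shear_stress
#' @param shear_dyn_cm2 Target wall shear stress, dyn/cm^2 (vectorised).
#' @return Volumetric flow rate in mL/min.
#' @examples
#' shear_to_flow(ibidi_channel("VI_0.4"), 0.32)  # ~0.18 mL/min
#' @export
shear_to_flow <- function(geom, shear_dyn_cm2, viscosity_P = 0.01,
                          method = c("series", "plates"),
                          modes = 101, tol = 1e-8) {
  if (any(shear_dyn_cm2 < 0))
    abort("`shear_dyn_cm2` must be non-negative.", class = "windsock_invalid_flow")
  unit_tau <- wall_shear_stress(geom, 1, viscosity_P, method, modes, tol)
  shear_dyn_cm2 / unit_tau
}

#' Flow velocity felt by a wall-anchored rod at a given shear stress
#'
#' Maps wall shear stress to the drive velocity used by the rod model. Two
#' conventions:
#' \describe{
#'   \item{`"near_wall"` (default)}{The rod lies inside the linear shear layer
#'     at the wall; the velocity at its centreline height h is
#'     \eqn{U = \tau h / \mu}. Default height 25 nm (tube radius plus linker).}
#'   \item{`"mean"`}{Cross-section mean velocity of the flow producing that
#'     stress, U = Q/(H W).}
#' }
#'
#' @inheritParams shear_to_flow
#' @param velocity_model `"near_wall"` or `"mean"`.
#' @param wall_offset_nm Rod centreline height above the wall for the
#'   near-wall model, nm.
#' @return Velocity in m/s (SI, ready for the simulation functions).
#' @export
shear_to_velocity <- function(geom, shear_dyn_cm2, viscosity_P = 0.01,
                              velocity_model = c("near_wall", "mean"),
                              wall_offset_nm = 25) {
  velocity_model <- match.arg(velocity_model)
  if (velocity_model == "near_wall") {
    tau_Pa <- shear_dyn_cm2 * 0.1
    mu_Pa_s <- viscosity_P * 0.1
    tau_Pa * (wall_offset_nm * 1e-9) / mu_Pa_s
  } else {
    q <- shear_to_flow(geom, shear_dyn_cm2, viscosity_P)
    mean_velocity(geom, q) / 100  # cm/s -> m/s
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
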