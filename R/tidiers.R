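#' Tidy a decay fit
#'
#' @param x A [fit_decay()] result.
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @method tidy windsock_decay_fit
#' @export
tidy.windsock_decay_fit <- function(x, ...) {
  tibble(term = c("a", "b"),
         estimate = c(x$a, x$b),
         std.error = c(x$se_a, x$se_b),
         conf.low = c(x$ci_a[1], x$ci_b[1]),
         conf.high = c(x$ci_a[2], x$ci_b[2]))
}

#' @rdname tidy.windsock_decay_fit
#' @method glance windsock_decay_fit
#' @export
glance.windsock_decay_fit <- function(x, ...) {
  tibble(sigma = x$sigma, nobs = x$n, method = x$method,
         conf.level = x$conf_level)
}

#' Tidy a colocalization result
#'
#' @param x A [randomized_null()] result.
#' @param ... Unused.
#' @return Tibble with the observed fraction, null summary and p-value.
#' @method tidy windsock_coloc
#' @export
tidy.windsock_coloc <- function(x, ...) {
  tibble(observed = x$observed, null_mean = x$null_mean,
         null_sd = x$null_sd, p.value = x$p_value,
         n_perm = x$n_perm, radius_um = x$radius_um)
}

#' @rdname tidy.windsock_coloc
#' @method glance windsock_coloc
#' @export
glance.windsock_coloc <- function(x, ...) tidy.windsock_coloc(x, ...)

#' Tidy a calibration curve
#'
#' @param x A [build_calibration()] result.
#' @param ... Unused.
#' @return The per-stress summary tibble.
#' @method tidy windsock_calibration
#' @export
tidy.windsock_calibration <- function(x, ...) x$curve

#' @rdname tidy.windsock_calibration
#' @method glance windsock_calibration
#' @export
glance.windsock_calibration <- function(x, ...) {
  tibble(n_stresses = nrow(x$curve), n_rods = x$curve$n_rods[1],
         velocity_model = x$params$velocity_model,
         seed = x$params$seed)
}

#' Tidy a shear estimate
#'
#' @param x An [estimate_shear()] result.
#' @param ... Unused.
#' @return One-row tibble with the estimate, CI and saturation flag.
#' @method tidy windsock_shear_estimate
#' @export
tidy.windsock_shear_estimate <- function(x, ...) {
  tibble(estimate = x$tau_hat, conf.low = x$ci_lower,
         conf.high = x$ci_upper, saturated = x$saturated,
         phi_obs_deg = x$phi_obs_deg, n_observed = x$n_observed)
}

#' @rdname tidy.windsock_shear_estimate
#' @method glance windsock_shear_estimate
#' @export
glance.windsock_shear_estimate <- function(x, ...) tidy.windsock_shear_estimate(x, ...)

#' Plot a calibration curve
#'
#' Mean total angle against wall shear stress with the per-stress confidence
#' band and the individual rods.
#'
#' @param object A [build_calibration()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot windsock_calibration
#' @export
autoplot.windsock_calibration <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$shear_dyn_cm2, y = .data$phi_mean_deg)) +
    ggplot2::geom_jitter(data = object$rods,
                         ggplot2::aes(y = .data$phi_deg), width = 0.01,
                         alpha = 0.3, size = 0.8) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$phi_mean_deg - .data$ci_half_deg,
      ymax = .data$phi_mean_deg + .data$ci_half_deg)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wall shear stress (dyn/cm²)",
                  y = expression("mean total angle" ~ Phi ~ "(deg)")) +
    ggplot2::theme_minimal()
}

#' Plot a colocalization null distribution
#'
#' Histogram of the randomized-placement null with the observed fraction.
#'
#' @param object A [randomized_null()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot windsock_coloc
#' @export
autoplot.windsock_coloc <- function(object, ...) {
  ggplot2::ggplot(tibble(null = object$null_fractions),
                  ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "colocalized fraction (null)", y = "count",
                  subtitle = sprintf("observed %.3f, p = %.4g",
                                     object$observed, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot a decay fit
#'
#' Data points and the fitted exponential.
#'
#' @param object A [fit_decay()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot windsock_decay_fit
#' @export
autoplot.windsock_decay_fit <- function(object, ...) {
  grid <- tibble(time_h = seq(0, max(object$data$time_h), length.out = 200))
  grid$fraction <- object$a * exp(-object$b * grid$time_h)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time_h, y = .data$fraction)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::labs(x = "time (h)", y = "fraction remaining") +
    ggplot2::theme_minimal()
}

#' Plot one or more azimuth trajectories
#'
#' @param traj A trajectory tibble (optionally with a `rod` column).
#' @param wrap Plot wrapped angles in (-pi, pi] instead of unwrapped?
#' @return A ggplot.
#' @export
plot_trajectory <- function(traj, wrap = FALSE) {
  d <- as_tibble(traj)
  if (!"rod" %in% names(d)) d$rod <- 1L
  if (wrap) d$phi_rad <- wrap_angle(d$phi_rad)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$phi_rad,
                                  group = .data$rod)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "time (s)", y = expression(phi ~ "(rad)")) +
    ggplot2::theme_minimal()
}
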