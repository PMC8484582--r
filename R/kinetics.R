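#' Pseudo-first-order attachment rate per cell
#'
#' Well-mixed encounter rate of nanostructures with cell-surface receptors:
#' \eqn{k_{on} \cdot C \cdot N}, reported per hour. This is the
#' back-of-envelope statistic behind anchoring-feasibility arguments: at the
#' slow SpyTag--SpyCatcher rate constant (1400 /M/s), 64 pM structures and
#' 1e4 receptors per cell it gives order one attachment event per cell per
#' hour, while antibody- or DNA-hybridisation-speed reactions (1e5--1e6
#' /M/s) give thousands.
#'
#' @param k_on_M_s Forward rate constant, 1/(M s).
#' @param conc_M Free nanostructure concentration, M.
#' @param n_receptors Available receptors per cell.
#' @param k_on_cap_M_s Optional diffusion-limited ceiling applied to
#'   `k_on_M_s` (e.g. from [diffusion_limited_k_on()]).
#' @return Expected attachment events per cell per hour.
#' @examples
#' attachment_rate(1400, 64e-12, 1e4)  # ~3.2 per hour
#' @export
attachment_rate <- function(k_on_M_s, conc_M, n_receptors,
                            k_on_cap_M_s = NULL) {
  if (any(c(k_on_M_s, conc_M, n_receptors) < 0))
    abort("Rates, concentrations and counts must be non-negative.",
          class = "windsock_domain_error")
  k <- if (is.null(k_on_cap_M_s)) k_on_M_s else pmin(k_on_M_s, k_on_cap_M_s)
  k * conc_M * n_receptors * 3600
}

#' Smoluchowski diffusion-limited association ceiling
#'
#' \eqn{k_{diff} = 4 \pi (D_A + D_B) a N_A}, converted to 1/(M s). Exposed as
#' an optional cap for [attachment_rate()]; the default well-mixed model does
#' not apply it.
#'
#' @param d_sum_um2_s Sum of the two species' diffusion coefficients, um^2/s.
#' @param radius_nm Encounter radius, nm.
#' @return Rate constant in 1/(M s).
#' @export
diffusion_limited_k_on <- function(d_sum_um2_s, radius_nm) {
  4 * pi * (d_sum_um2_s * 1e-12) * (radius_nm * 1e-9) * 6.02214076e23 * 1e3
}

#' Equilibrium bound fraction of a receptor site
#'
#' Single-site Langmuir occupancy \eqn{C / (C + K_d)}. Explains why >nM
#' affinity antibodies cannot retain structures supplied at picomolar
#' concentrations, while a 15-nt DNA duplex (sub-picomolar Kd) can.
#'
#' @param conc_M Ligand concentration, M.
#' @param kd_M Dissociation constant, M.
#' @return Bound fraction in \[0, 1\].
#' @examples
#' equilibrium_occupancy(64e-12, 1e-9)   # antibody regime: ~0.06
#' equilibrium_occupancy(16e-12, 1e-13)  # short-duplex regime: ~0.994
#' @export
equilibrium_occupancy <- function(conc_M, kd_M) {
  if (any(conc_M < 0) || any(kd_M < 0))
    abort("`conc_M` and `kd_M` must be non-negative.",
          class = "windsock_domain_error")
  if (any(conc_M + kd_M == 0))
    abort("Occupancy undefined when both `conc_M` and `kd_M` are zero.",
          class = "windsock_undefined_error")
  conc_M / (conc_M + kd_M)
}

#' Effective off-rate of a multivalent anchor
#'
#' Minimal avidity model for an anchor presenting `n_sites` independent
#' binding sites with local rebinding: full release requires every site to be
#' simultaneously free, and a transiently free site rebinds at rate
#' `rebind_s` before the remaining sites let go. The per-site release
#' probability is \eqn{p = k_{off} / (k_{off} + k_{rebind})} and
#' \deqn{k_{off}^{eff} = k_{off} \; p^{\,n-1}.}
#' Monotone decreasing in both valency and rebinding rate; with no rebinding
#' there is no avidity.
#'
#' @param k_off_single_s Single-site off-rate, 1/s.
#' @param n_sites Number of binding sites (>= 1).
#' @param rebind_s Local rebinding rate of a free site, 1/s.
#' @return Effective off-rate, 1/s.
#' @examples
#' multivalent_retention(1e-3, 6, 9e-3)  # 1e5-fold slower release
#' @export
multivalent_retention <- function(k_off_single_s, n_sites, rebind_s) {
  if (any(n_sites < 1))
    abort("`n_sites` must be >= 1.", class = "windsock_domain_error")
  if (any(k_off_single_s < 0) || any(rebind_s < 0))
    abort("Rates must be non-negative.", class = "windsock_domain_error")
  p_release <- ifelse(k_off_single_s + rebind_s == 0, 1,
                      k_off_single_s / (k_off_single_s + rebind_s))
  k_off_single_s * p_release^(n_sites - 1)
}

#' Dissociation constant of a DNA duplex from its standard free energy
#'
#' \eqn{K_d = \exp(\Delta G^\circ / (R T))} with \eqn{\Delta G^\circ} per
#' mole of duplex formed (negative for a stable duplex). A 15-nt duplex at
#' physiological temperature has \eqn{\Delta G^\circ} around -17 kcal/mol,
#' i.e. a sub-picomolar Kd. Takes the free energy as input; nearest-neighbour
#' sequence thermodynamics are out of scope.
#'
#' @param dG_kcal_mol Standard free energy of duplex formation, kcal/mol.
#' @param temperature_K Temperature, K (default 310.15, i.e. 37 degC).
#' @return Kd in M.
#' @examples
#' duplex_kd(-17)  # ~1e-12 M
#' @export
duplex_kd <- function(dG_kcal_mol, temperature_K = 310.15) {
  exp(dG_kcal_mol / (.R_kcal * temperature_K))
}

#' Fit an exponential decay to surface-persistence data
#'
#' Nonlinear least squares of \eqn{y = a e^{-b t}} with both parameters
#' constrained non-negative (Levenberg--Marquardt via minpack.lm), as used
#' for the fraction of seeds or seeded nanotubes remaining on the cell
#' surface over time. Starting values come from a log-linear regression on
#' the positive observations; if the NLS engine fails, that log-linear fit is
#' returned with `method = "log-linear"` and a warning.
#'
#' @param series A data frame with columns `time_h` and `fraction`
#'   (optionally a `cell` column; all cells are pooled in one fit).
#' @param conf_level Confidence level for the asymptotic (t-based) CIs.
#' @return An object of class `windsock_decay_fit`: list with `a`, `b`
#'   (1/h), standard errors, `conf_level` CIs, residual `sigma`, `n`,
#'   `method`, and the underlying fit object.
#' @examples
#' d <- tibble::tibble(time_h = seq(0, 2, 0.25),
#'                     fraction = exp(-2 * seq(0, 2, 0.25)))
#' fit_decay(d)
#' @export
fit_decay <- function(series, conf_level = 0.95) {
  if (!is.data.frame(series) || !all(c("time_h", "fraction") %in% names(series)))
    abort("`series` must have columns `time_h` and `fraction`.",
          class = "windsock_domain_error")
  d <- series[is.finite(series$time_h) & is.finite(series$fraction), ]
  if (nrow(d) < 3)
    abort("Need at least 3 observations to fit a decay.",
          class = "windsock_domain_error")
  if (!any(abs(d$time_h) < 1e-9))
    abort("`series` must include the t = 0 normalisation point.",
          class = "windsock_domain_error")
  pos <- d$fraction > 0
  start <- if (sum(pos) >= 2) {
    cf <- coef(stats::lm(log(fraction) ~ time_h, data = d[pos, ]))
    list(a = exp(unname(cf[1])), b = max(0, -unname(cf[2])))
  } else list(a = max(d$fraction), b = 1)

  fit <- tryCatch(
    minpack.lm::nlsLM(fraction ~ a * exp(-b * time_h), data = d,
                      start = start, lower = c(a = 0, b = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  n <- nrow(d)
  tcrit <- qt(1 - (1 - conf_level) / 2, df = n - 2)
  if (is.null(fit)) {
    warn("Nonlinear fit did not converge; returning log-linear fallback.",
         class = "windsock_fit_warning")
    lmfit <- stats::lm(log(pmax(fraction, 1e-12)) ~ time_h, data = d)
    cf <- coef(lmfit); se <- sqrt(diag(vcov(lmfit)))
    a <- exp(unname(cf[1])); b <- -unname(cf[2])
    se_a <- a * se[1]; se_b <- se[2]
    method <- "log-linear"; sigma <- summary(lmfit)$sigma
  } else {
    cf <- coef(fit)
    se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA, NA))
    a <- unname(cf["a"]); b <- unname(cf["b"])
    se_a <- unname(se[1]); se_b <- unname(se[2])
    method <- "nls"; sigma <- summary(fit)$sigma
  }
  structure(list(a = a, b = b, se_a = se_a, se_b = se_b,
                 ci_a = a + c(-1, 1) * tcrit * se_a,
                 ci_b = b + c(-1, 1) * tcrit * se_b,
                 sigma = sigma, n = n, conf_level = conf_level,
                 method = method, fit = fit, data = as_tibble(d)),
            class = "windsock_decay_fit")
}

#' @export
print.windsock_decay_fit <- function(x, ...) {
  cat(sprintf(paste0("<windsock_decay_fit> y = a exp(-b t): a = %.4g ",
                     "[%.4g, %.4g], b = %.4g [%.4g, %.4g] /h (%s, n = %d)\n"),
              x$a, x$ci_a[1], x$ci_a[2], x$b, x$ci_b[1], x$ci_b[2],
              x$method, x$n))
  invisible(x)
}
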