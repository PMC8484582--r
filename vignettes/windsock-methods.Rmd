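---
title: "Anchored-nanotube flow sensing: models, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored-nanotube flow sensing: models, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(windsock)
```

This vignette is the package's own account of the science it implements:
the tethered-rod model and its assumptions, the statistics built on top of
it, the numerical choices, and what the synthetic-data generators do and do
not emulate.

## The tethered rod in shear flow

A DNA tile nanotube of contour length ℓ ≈ 5 µm has a persistence length of
8.7 µm, so over these lengths it behaves approximately as a rigid rod; the
package adopts the rigid-rod idealisation throughout and ignores bending
modes. The rod is anchored at one end by its origami seed through an
antibody/DNA linker that is treated as a *free swivel* — no torsional
stiffness is applied, because the linker chemistry gives no reason to
expect a preferred azimuth.

With the polar angle pinned at the wall (the two-angle simulator
`simulate_spherical()` justifies this: under drive the polar deviation from
the wall plane is half-normal with σ = 1/√κ, i.e. small except at very weak
flow), the dynamics reduce to the azimuth φ between rod and flow. Drag on
the rod in a uniform flow of speed U is F = (αµUℓ, 0) applied at the centre
of mass r = (ℓ/2 cos φ, ℓ/2 sin φ), so the torque is

$$M(\varphi) = -\tfrac12 \alpha \mu U \ell^2 \sin\varphi ,$$

and the overdamped rotational Langevin equation is γ dφ/dt = M + R with
thermal noise R.

**Drag coefficients.** Defaults come from slender-body theory:
α = 4π/(ln(ℓ/d) + 0.84) and γ = πµℓ³/(3(ln(ℓ/d) − 0.66)), with hydrodynamic
diameter d = 12 nm for these tubes. For the default 5 µm rod in water this
gives γ ≈ 2.4 × 10⁻²⁰ J s and a rotational diffusion coefficient
D = k_BT/γ ≈ 0.17 rad²/s at 293 K. Both coefficients can be overridden in
`rod_params()`; wall corrections to drag are not modelled.

**Noise convention.** Requiring the fluctuation–dissipation relation,
Var(R) = 2 k_B T γ/Δt, makes the stationary law exactly Boltzmann,
p(φ) ∝ exp(κ cos φ) — von Mises with κ = αµUℓ²/(2k_BT). This is the
default (`noise_convention = "fdt"`). A literal reading of the model's
stated noise density, P(R) ∝ exp[−R²Δt/(2k_BTγ)], implies half that
variance and equilibrates to temperature T/2; it is retained as
`"as_printed"` for comparison, but only the FDT form is self-consistent
with the physics the torque expression encodes, so every statistic in the
package defaults to it.

**Which velocity does the rod feel?** The calibration maps wall shear
stress τ to a drive velocity. Two conventions are available in
`shear_to_velocity()`:

* `"near_wall"` (default): the rod lies inside the linear shear layer, so
  the velocity at its centreline height h is U = τh/µ. The default
  h = 25 nm is the tube radius plus a linker allowance. With slender-body
  drag this puts κ ≈ 14 per dyn/cm² for the default rod — a dynamic range
  spanning wide angular exploration at 0.05 dyn/cm² to tight alignment at
  2 dyn/cm², matching the regime in which such sensors are useful.
* `"mean"`: the cross-section mean velocity U = Q/(HW). For a rod only tens
  of nanometres above the wall this overestimates the drive by roughly four
  orders of magnitude and would saturate the sensor below 0.01 dyn/cm²; it
  is provided because the mean velocity is the natural scale when the
  object of interest sits in the channel bulk.

The choice of h is a genuine model parameter: it sets the sensor's gain and
is deliberately exposed (`wall_offset_nm`) and logged with every
calibration.

## Numerical integration

`simulate_trajectory()` uses Euler–Maruyama with R's RNG (so trajectories
are reproducible bit-for-bit from seed plus parameters; populations derive
per-rod substream seeds from one master seed). Writing a = ½αµ|U|ℓ²/γ for
the deterministic relaxation rate, the default step is
Δt = min(0.1/a, 1 ms) and steps larger than 0.5/a are refused with a
suggestion of a safe step, since beyond that the sin-drift discretisation
destabilises. For stationary-law work `sample_stationary()` thins a long
run; the acceptance workloads use a fixed dimensionless step aΔt = 0.02
(stationary-variance bias ≈ aΔt/2 = 1%) and a thinning lag of 5/a
(autocorrelation e⁻⁵), which keeps the Kolmogorov–Smirnov distance to the
closed-form law well under 0.01 at 10⁵ samples. At U = 0 the scheme is
exact for any step (pure Gaussian increments), which the zero-flow sampler
exploits with one long-jump step per retained sample.

Angles are stored unwrapped; wrapping to (−π, π] happens only inside
statistics (`wrap_angle()`, circular range, densities).

## The total-angle statistic Φ

The experimental readout is the angular range a nanotube sweeps over 30
frames taken every 5 s, read from a maximum time projection. The package
formalises Φ as the *circular range* of the frame-sampled orientations:
360° minus the largest empty arc between the sorted wrapped samples, capped
at 360°. Φ is a set statistic — invariant to frame order and to global
rotation — which sidesteps any ambiguity about how arcs longer than 180°
between consecutive frames would be counted.

Two protocol-level effects matter when interpreting Φ:

* **Discretisation ceiling.** With n discrete frames the expected largest
  empty arc is non-zero even for a rod that explores uniformly: for 30
  i.i.d. uniform frames E[Φ] ≈ 312°, and for the correlated random walk the
  default rod executes at rest over 145 s, simulation gives E[Φ] ≈ 304°
  (sd ≈ 20° per rod). "Explores all azimuths" therefore reads as a
  population mean around 300°, not literally 360°; the acceptance checks
  assert the zero-flow mean exceeds 280°.
* **Flow-on equilibration.** If the trajectory starts from the no-flow
  uniform distribution at frame 0, a strongly driven rod sweeps from its
  initial angle to the aligned mode *inside* the acquisition window and Φ
  records that transit (population mean ≈ E|φ₀| ≈ 90–100° regardless of
  stress), destroying the monotone stress response. Experimentally the
  pump runs before acquisition starts, so `build_calibration()` and
  `gen_angle_dataset()` simulate an equilibration period (default 60 s,
  ≥ 7 relaxation times at the weakest calibrated stress) before the
  protocol window.

## Calibration and inversion

`build_calibration()` simulates `n_rods` independent rods per stress (the
cohort default is 15, matching the per-stress sample size of the flow
experiments), applies the protocol, and records per-rod Φ. Because the
curve is estimated by Monte Carlo it need not be exactly monotone;
`estimate_shear()` therefore applies isotonic regression (non-increasing)
before interpolating. The confidence interval is a Neyman belt: at each
calibration stress the sampling distribution of a mean over `n_observed`
rods is bootstrapped from the per-rod pool, and the CI is the stress range
whose belt contains the observation. Observations above the curve's
low-stress plateau saturate at the lowest calibrated stress with a
`saturated` flag and a warning (the sensor cannot distinguish "very weak"
from "no" flow); observations below the calibrated range raise an
extrapolation error — the sensor's dynamic-range limit, about
0.05–2 dyn/cm² for the default rod.

Rod-length heterogeneity is available as a sensitivity knob
(`length_dist`): real nanotube populations are polydisperse, and since
κ ∝ ℓ², length variation widens the per-stress Φ spread. The default keeps
ℓ fixed so that calibration spread isolates thermal noise.

## Synthetic imaging and the automated projection readout

`render_frame()` draws the rod as the exact line integral of an isotropic
Gaussian PSF (transverse Gaussian profile with error-function end caps),
adds a constant background, Poisson shot noise and Gaussian read noise.
Defaults (0.1 µm/px, PSF σ = 1.5 px, amplitude 500 over background 100,
read noise 20) give a peak SNR well above 5. The measurement chain mirrors
the manual workflow: per-frame Gaussian blur of σ = 1.00 px, pixelwise
maximum time projection, then `measure_angle_extent()`:

1. Otsu threshold on the normalised projection (a fixed-quantile threshold
   is the low-SNR fallback);
2. restrict to an annulus around the anchor (0.3–1.15 ℓ) where a pixel's
   polar angle is well defined;
3. intensity-weighted 5° polar histogram; a bin counts as visited if it
   carries at least half the maximum bin weight (an FWHM-style criterion
   that rejects PSF tails bleeding into neighbouring bins);
4. Φ = circular range of the visited bins.

The 5° bin width sits below the agreement tolerance against the
trajectory-based Φ; on noiseless synthetic projections the estimator reads
a static rod as ≤ 10° (its intrinsic angular width) and a 90° fan as
95°, and across κ ∈ {0.5, 2, 10} at default SNR the image-based and
trajectory-based Φ agree to well within 15°. That tolerance is an
engineering choice for the automated reader — the manual measurements it
replaces have unquantified reader error.

## Attachment kinetics and surface persistence

The feasibility calculations are deliberately minimal, matching their
back-of-envelope role:

* `attachment_rate()` is the well-mixed pseudo-first-order product
  k_on·C·N (per hour). For the slow covalent-tag scenario
  (k_on = 1400 M⁻¹s⁻¹, C = 64 pM, N = 10⁴ receptors) it gives ≈ 3.2
  events/cell/h — order one, which is the level of agreement such an
  estimate supports; an optional Smoluchowski ceiling
  (`diffusion_limited_k_on()`) can cap k_on, but no diffusion limitation is
  applied by default.
* `equilibrium_occupancy()` is single-site Langmuir C/(C + K_d): at
  picomolar ligand, >nM-affinity antibodies sit mostly unbound while a
  sub-picomolar-K_d 15-nt duplex stays bound.
* `multivalent_retention()` models avidity as independent sites with local
  rebinding: effective off-rate k_off·p^(n−1) with release probability
  p = k_off/(k_off + k_rebind). No cooperative or geometric effects — the
  source experiments motivate only the qualitative "effectively
  irreversible" claim.
* `duplex_kd()` converts a formation free energy to K_d = exp(ΔG°/RT);
  nearest-neighbour sequence thermodynamics are out of scope, so ΔG° is an
  input.

`fit_decay()` fits y = a·e^(−bt) by Levenberg–Marquardt NLS with a, b ≥ 0,
asymptotic t-based confidence intervals, and a log-linear fallback if the
NLS engine fails. Single-exponential only: the persistence measurements do
not distinguish detachment from internalisation, so a two-population model
would not be identifiable. The generator (`gen_decay_dataset()`) produces
per-cell fractions with additive Gaussian noise (default sd 0.02), clipped
at zero and renormalised so fraction(0) = 1, over 6 cells. Sampling grids:
every 10 min over 70 min for the fast (seed) series; the slow (nanotube)
series needs a longer window to constrain b ≈ 0.5/h, and the generator's
default there is 15-min sampling over 3 h. At these designs the fitted
rate is unbiased to within 3% and the nominal 95% CIs cover the generating
rate at close to nominal rate (both checked in the test suite).

## Colocalization

`coloc_fraction()` counts seeds with at least one antibody localisation
within radius r (default 0.5 µm ≈ two confocal pixels at 60×; the radius
is a required, logged analysis parameter, since any criterion radius is to
some degree conventional). The null emulates stochastic attachment:
`randomized_null()` redraws the seed positions uniformly inside the cell
mask (antibodies stay fixed), and the permutation p-value uses the add-one
rule. On a homogeneous Poisson antibody pattern of intensity λ both the
observed fraction for uniform seeds and the randomization null equal the
void probability 1 − exp(−λπr²), which provides a closed-form oracle; the
permutation p-value is uniform under the null by construction, and the test
suite checks its calibration empirically. Spot detection from images is out
of scope — patterns arrive as coordinates, and `gen_coloc_dataset()` plants
a controllable truly-colocalized fraction inside a rasterised cell mask
(default 30 × 20 µm ellipse at 0.1 µm/px, a typical adherent-cell
footprint).

## Channel hydrodynamics

`wall_shear_stress()` evaluates the exact series solution for fully
developed laminar flow in a rectangular duct. For height h ≤ width w and
pressure gradient G, the flow rate is Q = h³wG·F_p/(12µ) with
F_p = 1 − Σ_odd 192h/(π⁵n⁵w)·tanh(nπw/2h), and the bottom-wall centreline
stress is τ = (4hG/π²)·Σ_odd (1 − sech(nπw/2h))/n². The shear sum is
evaluated through Σ_odd 1/n² = π²/8 so that only the exponentially decaying
sech tail is truncated; 101 odd modes with a 10⁻⁸ relative tolerance is far
more than needed at these aspect ratios, and the truncation is checked at
run time. As w/h → ∞ both factors approach 1 and τ → 6µQ/(wh²), the
parallel-plate formula exposed as `method = "plates"`; at the slides'
aspect ratio of 9.5 the series stress exceeds the plate value by ≈ 7%.
Entrance effects, pulsatility and non-Newtonian media are out of scope.
Default viscosities are water-like: 0.01 P at 20 °C, 0.0069 P at 37 °C,
always overridable since perfusates vary.

## What the generators emulate — and what they do not

The synthetic data carry the statistical structure the analyses assume:
Markovian rotational dynamics with the exact stationary family, wrapped
Gaussian angle-measurement noise (default 3°), exponential per-cell decay
with homoscedastic noise, and planted colocalized fractions over Poisson
backgrounds. They do **not** emulate: curved or moving cell surfaces (the
substrate is flat and the anchor static), filament flexibility or
out-of-plane bending at rest, photobleaching or focus drift, antibody
clustering, receptor turnover, or reader variability in the manual angle
measurement. Passing recovery tests on these generators therefore
demonstrates the *estimators* are correct and calibrated under the stated
model, not that the model captures every feature of real micrographs.

## Problem sizes

The test and acceptance workloads use: 10⁵ decorrelated samples per
concentration for the stationary law; 15 rods per stress for calibration
(200 per stress for the inversion belt) over the 0.05–2 dyn/cm² grid; 200
synthetic cohorts per decay design; 100 inversion replicates; 10⁴-point
patterns for the closed-form colocalization checks and 200 replicates for
p-value calibration; and 9 rendered time-lapse stacks (3 per κ) for the
imaging comparison. These sizes make the Monte-Carlo error small against
every tolerance asserted while keeping a full run in minutes on one core.

## Known limitations

* The near-wall drive height h is not measurable within the package; the
  calibration gain scales linearly with it, so cross-sample comparisons
  should hold h fixed and treat absolute stress estimates as conditional
  on it.
* Hydrodynamic coupling to the wall (drag enhancement near a no-slip
  boundary) is neglected; it would slow the dynamics but not change the
  stationary law.
* The avidity model ignores site geometry and tether strain.
* The imaging module renders a single filament per field; crowded fields,
  crossing filaments and segmentation of real micrographs are out of scope.
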