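---
title: "Models and methods behind aerotrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aerotrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerotrack)
```

`aerotrack` analyses Rayleigh-scattering microscopy data of focused
aerosol nanoparticle beams: double-exposure frames in, particle positions,
velocities, diameters and beam-level statistics out. This vignette
explains the models the package implements, the parameters that matter,
the numerical choices, and what the synthetic-data tests do and do not
demonstrate.

## The measurement model

A double-pulsed laser (532 nm, ~0.5 mm FWHM spot, energies up to ~100 mJ)
illuminates particles as they leave the injector; a microscope images the
scattered light onto a 2048×2048 sensor at an object-plane scale of
1.14 µm/px. Each exposure contains two images of every moving particle,
separated by `velocity × pulse_delay`.

For particles small compared with the wavelength (here taken as
d ≤ 200 nm) the scattering is Rayleigh-like and the detected signal is

$$I = k\, d^6\, E_\mathrm{pulse}\, I_\mathrm{rel}(x, y),$$

with `k` an empirical constant absorbing the optical throughput, quantum
efficiency and scattering cross-section prefactor, and
$I_\mathrm{rel}$ the relative illumination of the Gaussian laser profile.
The package's default `k` is anchored to the instrument's benchmark
sensitivity: a 40 nm polystyrene sphere yields 157 detected photons per
50 mJ pulse at the beam center. The d⁶ law means a factor 2 in diameter
is a factor 64 in signal — which is also why 20 nm spheres (3 photons)
drown in a background whose per-pixel fluctuations are larger than that.

## Synthetic frames

`render_frame()` is the forward model used throughout the test suite:

- **Spots** are pixel-integrated isotropic Gaussians (σ = 2 px default).
  The instrument's PSF is not published; the diffraction-limited Airy
  radius of the NA 0.055 objective at 532 nm is ≈5.9 µm ≈ 5 px at the
  default pixel scale, so a few-pixel Gaussian is the right order. The
  value is configurable and photon totals are exact (pixel integrals use
  the Gaussian CDF, conserving photons to the truncation of the ±6σ
  window).
- **Background** is Poisson with mean `0.12 photons/px/mJ × total pulse
  energy`; **dark noise** is additive Gaussian with σ = 1.3 photons.
  Negative pixels are clamped at zero and values clip at the saturation
  level (30 700 photons).
- **Ghosts**: back reflection in the optics duplicates each spot at a
  constant pixel offset with a configurable intensity fraction (default
  0.1, "faint"). Ghosts are only rendered when their peak pixel would
  exceed one dark-noise σ. The offset magnitude is not documented for the
  real instrument; tests use an arbitrary configured value and check
  recovery against it.
- **Clusters**: nebulizer droplets hold a Poisson number of particles, so
  conditioned on holding at least one, occupancy is zero-truncated
  Poisson (`sample_cluster_sizes()`). A dried n-mer is modeled as one
  sphere of diameter `d·n^{1/3}` (volume conservation), hence a dimer is
  1.26× oversize and 4× brighter.
- Motion during one ~7 ns pulse (≲0.6 px at 100 m/s) is not rendered; it
  is a known, sub-pixel blur source.

What passing tests on these frames show: the pipeline's detection,
localization, photometry, pairing and fitting logic is correct against a
known forward model. What they do not show: robustness to real-world
effects absent from the model — defocus across the depth of field,
speckle, non-Gaussian stray-light structure, drifting illumination, or
Mie-regime departures from d⁶ above ~200 nm.

## Detection choices

The difference-of-Gaussians filter uses σ = 3 and 6 px. (The source
material for this instrument prints 0.03/0.06 px, which would make both
blurs numerical identities; we read this as a unit misprint and keep the
ratio-2 pair at the spot scale, fully configurable.) The signed DoG image
is thresholded; the threshold is deliberately a required, manual
configuration value, as on the instrument — `suggest_threshold()` offers
mean + 5σ of a particle-free DoG region as a starting point.
Supra-threshold pixels are grouped by 4-connectivity (configurable to 8).

The spot position is the center of mass of the **raw** pixel values of the
selected cluster. Weighting by DoG values instead was considered and
rejected on measurement: the negative annulus that the DoG imprints around
a bright spot biases the centroid of a faint neighbor (a ghost 15 px away
shifts by ~1.3 px with DoG weights, ~0.5 px with raw weights), enough to
break ghost-offset recovery at 1 px accuracy.

Brightness is the raw-pixel integral within 10 px of the centroid (317
pixels); no background subtraction by default, with annulus-median
subtraction available (`annulus_subtract`). For faint particles the
included background is a noticeable positive bias (≈1900 photons over the
disk at 50+50 mJ), so sizing-grade photometry should enable the annulus
option or operate at thresholds where spots dominate. Saturation anywhere
in the disk flags the record as unsizable: the d⁶ law cannot be inverted
outside the sensor's linear range.

Peaks closer than 21 px (strict inequality) are mutually excluded;
ghost-flagged peaks are removed first so that a ghost cannot veto its own
parent. One practical consequence, true of the instrument as well: the
two flash images of one particle must land ≥21 px apart, so delay and
expected speed must be chosen together.

## Velocimetry

Pairing is mutual nearest neighbor over candidate displacements that
(a) point downstream (the injector points down; flash order is otherwise
unrecoverable from a single exposure) and (b) do not exceed
`max_speed × delay`, with `max_speed` defaulting to the 1000 m/s bound set
by the 0.5 mm spot and 0.5 µs delay. Near-ties are resolved towards the
frame's median candidate displacement. An optional brightness-similarity
gate exists but is off by default. Speeds are reported as magnitudes with
the flow-prior direction.

## Sizing and calibration

Calibration fits `I^{1/6} = k^{1/6} d` as a line through the origin —
linear least squares in sixth-root space, matching how such calibrations
are plotted and making the fit insensitive to the enormous dynamic range
of I itself. A free-exponent log–log fit is stored as a diagnostic; on
noiseless synthetic data it returns 6.000. Sizing inverts to
`d = (I/k)^{1/6}` and is only reported inside the configured sizing
window, default 40–125 nm: below it the signal sinks into background,
above it the detector saturates. The window is instrument configuration,
not physics, and is therefore a parameter.

Cluster flagging uses a diameter cutoff at 1.15× the monomer mode —
midway between monomer (1.00) and dimer (1.26). With ~5% sizing noise
this separates populations cleanly (≥90% of dimers caught at ≤5% monomer
loss in the seeded tests). The monomer mode is estimated as the
kernel-density mode when not supplied.

## Beam characterization

Transverse profiles are fitted as Gaussians by maximum likelihood on the
unbinned positions (histograms are display only). All widths are FWHM
throughout; σ↔FWHM conversion lives in exactly one place
(`fwhm_to_sigma()`). The width-vs-distance table is fitted with the
Gaussian-beam envelope

$$w(z) = w_0\sqrt{1 + \left(\frac{z - z_0}{z_R}\right)^2},\qquad
\theta = \frac{w_0}{2 z_R},$$

by Levenberg–Marquardt least squares. θ is the far-field half-angle of
the FWHM envelope (half- vs full-angle is a convention choice; it is
documented and trivially rescaled). When per-width uncertainties are
available, inverse-variance weights should be used: far-field widths are
proportionally noisier in absolute terms, and unweighted fits measurably
bias the recovered waist.

Pressure scaling laws are free-exponent log–log regressions. The source
material is internally inconsistent about the waist exponent (−2/3 in
text, −3/2 in the figure caption); the package takes no side and reports
the fitted exponent with its standard error. The synthetic generator's
default is −3/2 because only that value is consistent with the quoted
divergence (p⁻¹) and focus-distance (p⁻¹ᐟ²) laws under the Gaussian-beam
constraint z_R = w₀/(2θ).

Areal density is mean count per area per snapshot (each flash is an
independent snapshot); the peak column density comes from the fitted
transverse Gaussian. Injection yield compares beam outflow
(`peak density × √(2π)σ × speed`, equivalent to peak volume density ×
cross-section 2πσ² × speed under axisymmetry — "cross-sectional beam
area" is otherwise undefined) with solution inflow
(`concentration × flow rate`). The predicted hit ratio is
`density × π(FWHM/2)²`, the nominal-focus-area assumption; it is linear
in density, quadratic in focus size, and capped at 1 for reporting. Real
hit ratios can exceed this prediction substantially because the effective
focus area (the region intense enough to yield a detectable diffraction
pattern) need not match the nominal FWHM disk.

## Jet dynamics

Downstream of the 1.5 mm exit orifice the gas expands as a free jet. The
centerline Mach number uses the monatomic-gas far-field correlation with
A = 3.26 and x₀/d = 0.075; it is refused below x/d = 0.5 where the
correlation does not hold. Local gas states follow the isentropic
relations from the stagnation state (entrance pressure, room
temperature). The orifice mass flow F_m and gas density ρ_l come from an
isentropic choked-flow estimate at the effective throat — a deliberate,
documented simplification of the flow inside the lens; the
effective-to-physical diameter ratio (default 0.880) absorbs the orifice
boundary layer and can be refit from data
(`fit_entrance_parameters()`).

Drag on a particle uses Henderson's sphere correlation across flow
regimes, evaluated with the relative Mach and Reynolds numbers; in the
low-speed free-molecular limit it agrees with Epstein drag to within a
few percent (a test pins this at 10%). Particle surface temperature
defaults to the local gas temperature; a fixed wall temperature is
available. The equation of motion is integrated in space,
`m dv/dx = F/v`, by `lsoda` with a relative tolerance (default 1e-8);
the v = 0 singularity is avoided by requiring a positive entrance
velocity, itself a free parameter of the data fit. Tolerance refinement
changes terminal velocities by <0.1% (tested).

The Stokes number follows
`St = τu/(d_f/2)`, `τ = C_c ρ_p d_p²/(18µ)`, `u = 4F_m/(ρ_l π d_f²)`,
with C_c the **Cunningham slip correction**
`1 + Kn(1.257 + 0.4 e^{−1.1/Kn})` evaluated at the sonic orifice state —
the factor that belongs in the relaxation time, even though the
historical symbol is sometimes labeled a "discharge coefficient". Model
terminal velocities at equal St agree after normalization by the He speed
of sound to within 2% across pressure/diameter combinations (tested),
reproducing the empirical single-curve collapse. The collapse fit itself
takes a pluggable model form; the default is the saturating
three-parameter curve `v/c = B + (A−B)·C·St/(1 + C·St)` (low-St floor B,
high-St asymptote A, transition scale 1/C), chosen because the canonical
form is not reproducible from the available material.

## Problem sizes and determinism

The stochastic suites use sizes chosen to make their statistical
tolerances meaningful at interactive runtimes: 100 frames of 256² pixels
for detection recall/FDR, 1500 positions per (pressure, distance) cell
across 5 pressures × 10 distances for scaling-law recovery, 10⁵ draws for
distribution-level checks, and 25-point collapses for the nonlinear fits.
Every stochastic test and the simulator itself are seeded; identical
seeds give bit-identical frames and identical CSV outputs.

## Known limitations

- The photometric model is strictly Rayleigh; no Mie corrections above
  ~200 nm, where detection still works but sizing does not.
- The 25° laser/microscope geometry is metadata only; no parallax
  correction is applied (the dominant velocity component is perpendicular
  to both axes) and no oblique-illumination correction enters the
  brightness rescaling.
- The jet model is one-dimensional on the centerline: no barrel shock,
  Mach disk, or radial trajectories, and the in-lens flow is replaced by
  the choked-orifice estimate.
- The pipeline does not resolve overlapping particles beyond the 21 px
  exclusion rule.
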