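#' Gaussian fit to a transverse beam profile
#'
#' Maximum-likelihood Gaussian fit to unbinned transverse particle
#' positions (the sample mean and the MLE standard deviation); histograms
#' are for display only. Widths are reported as FWHM.
#'
#' @param positions transverse object-plane coordinates, um
#' @param min_count minimum number of positions required
#' @return list with `center` (um), `fwhm` (um), `sigma` (um), `n`, and
#'   `fwhm_se` (large-sample standard error of the FWHM)
#' @export
transverse_profile <- function(positions, min_count = 50) {
  x <- positions[!is.na(positions)]
  if (length(x) < min_count)
    stop("need at least ", min_count, " positions, got ", length(x))
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))       # MLE
  if (sigma == 0) stop("degenerate profile: all positions identical")
  list(center = mu, fwhm = sigma_to_fwhm(sigma), sigma = sigma,
       n = length(x),
       fwhm_se = sigma_to_fwhm(sigma / sqrt(2 * length(x))))
}

#' Fit a Gaussian-beam envelope to beam widths vs distance
#'
#' Nonlinear least squares of `w(z) = w0 * sqrt(1 + ((z - z0)/zR)^2)` to
#' measured FWHM widths at several injector distances. The divergence is
#' reported as the far-field half-angle of the FWHM envelope,
#' `theta = w0 / (2 zR)` (mrad when w is in um and z in mm).
#'
#' @param z injector distances, mm (>= 4 values spanning the focus)
#' @param fwhm beam FWHM at each distance, um
#' @param weights optional fit weights (e.g. 1/se^2)
#' @return object of class `beam_model`: `waist_fwhm` (um),
#'   `focus_distance` (mm), `rayleigh_range` (mm), `divergence` (mrad,
#'   FWHM half-angle), `widths` (input table with fitted values and
#'   residuals)
#' @export
fit_gaussian_beam <- function(z, fwhm, weights = NULL) {
  stopifnot(length(z) == length(fwhm), length(z) >= 4, all(fwhm > 0))
  z <- unname(z); fwhm <- unname(fwhm)
  if (is.null(weights)) weights <- rep(1, length(z))
  start <- list(w0 = max(min(fwhm), 1e-6),
                z0 = unname(z[which.min(fwhm)]),
                zR = max(diff(range(z)) / 4, 1e-3))
  fit <- minpack.lm::nlsLM(
    fwhm ~ w0 * sqrt(1 + ((z - z0) / zR)^2),
    start = start, weights = weights,
    lower = c(w0 = 1e-9, z0 = -Inf, zR = 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(
    waist_fwhm = unname(cf["w0"]),
    focus_distance = unname(cf["z0"]),
    rayleigh_range = unname(cf["zR"]),
    divergence = unname(cf["w0"] / (2 * cf["zR"])),
    widths = data.frame(z = z, fwhm = fwhm,
                        fitted = stats::fitted(fit),
                        residual = stats::resid(fit)),
    fit = fit
  ), class = "beam_model")
}

#' Fit a power-law pressure scaling
#'
#' Log-log linear regression `log y = log a + e log p` of a beam parameter
#' against the entrance pressure, returning the exponent with its standard
#' error.
#'
#' @param pressures entrance pressures, mbar (>= 3, positive)
#' @param values parameter values (positive)
#' @param quantity optional label ("waist", "focus_distance", "divergence")
#' @return object of class `scaling_law_fit`: `amplitude`, `exponent`,
#'   `exponent_se`, `quantity`
#' @export
fit_scaling_law <- function(pressures, values, quantity = NA_character_) {
  stopifnot(length(pressures) == length(values), length(pressures) >= 3)
  if (any(pressures <= 0) || any(values <= 0))
    stop("pressures and values must be positive")
  fit <- stats::lm(log(values) ~ log(pressures))
  sm <- summary(fit)$coefficients
  structure(list(amplitude = exp(unname(stats::coef(fit)[1])),
                 exponent = unname(stats::coef(fit)[2]),
                 exponent_se = unname(sm[2, 2]),
                 quantity = quantity),
            class = "scaling_law_fit")
}

#' Areal particle-number density
#'
#' Mean number of particles per unit area of the image plane, per single
#' snapshot (each laser flash is treated as an independent snapshot). When a
#' fitted transverse profile is supplied, the peak of the Gaussian column
#' density is also returned: `peak = N_per_frame / (sqrt(2 pi) sigma * L)`
#' with L the axial extent of the counting region.
#'
#' @param counts particles counted per frame (vector, one entry per frame)
#' @param area area of the counting region, um^2 (> 0)
#' @param profile optional [transverse_profile()] fit of the transverse
#'   positions in the region
#' @param axial_length axial extent of the counting region, um (needed with
#'   `profile`)
#' @return list with `mean_density` (particles/um^2) and, when `profile`
#'   is given, `peak_density` (particles/um^2 at the beam axis)
#' @export
areal_density <- function(counts, area, profile = NULL,
                          axial_length = NULL) {
  if (area <= 0) stop("area must be positive")
  if (length(counts) < 1) stop("need at least one frame")
  out <- list(mean_density = mean(counts) / area)
  if (!is.null(profile)) {
    if (is.null(axial_length) || axial_length <= 0)
      stop("axial_length required with a transverse profile")
    out$peak_density <- mean(counts) / (sqrt(2 * pi) * profile$sigma *
                                          axial_length)
  }
  out
}

#' Injection yield from solution into vacuum
#'
#' Ratio of the particle outflow in the vacuum beam to the particle inflow
#' supplied in solution. The outflow is `peak areal density x sqrt(2 pi)
#' sigma x speed` (equivalently: peak volume density x cross-sectional beam
#' area `2 pi sigma^2` x speed, under axisymmetry); the inflow is
#' `concentration x flow rate`.
#'
#' @param peak_density peak areal particle density, particles/um^2
#' @param sigma transverse Gaussian sigma of the beam, um
#' @param speed mean particle speed, m/s
#' @param concentration particle concentration of the solution, per ml
#' @param flow_rate sample flow rate, ul/min
#' @return yield (fraction); a warning is raised above 1
#' @export
injection_yield <- function(peak_density, sigma, speed, concentration,
                            flow_rate) {
  stopifnot(peak_density >= 0, sigma > 0, speed > 0, concentration > 0,
            flow_rate > 0)
  outflow <- peak_density * sqrt(2 * pi) * sigma * m_to_um(speed)  # per s
  inflow <- concentration / 1000 * flow_rate / 60                  # per s
  y <- outflow / inflow
  if (y > 1) warning("yield above 1: unphysical, check calibration")
  y
}

#' Predicted hit ratio for a nominal X-ray focus
#'
#' Probability that an X-ray pulse intercepts a particle, assuming the
#' effective focus area equals the nominal area `pi (FWHM/2)^2`:
#' `hit ratio = areal density x focus area`. Linear in density, quadratic
#' in the FWHM; reported values are capped at 1.
#'
#' @param areal_density particles/um^2
#' @param focus_fwhm X-ray focus FWHM, um
#' @return hit ratio (fraction, capped at 1)
#' @export
predict_hit_ratio <- function(areal_density, focus_fwhm) {
  stopifnot(all(areal_density >= 0), all(focus_fwhm > 0))
  pmin(1, areal_density * pi * (focus_fwhm / 2)^2)
}
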