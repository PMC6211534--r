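#' @name units
#' @title Unit conversions and width conventions
#'
#' @description Centralized unit conversions used throughout the package.
#' Internally all physics is done in SI; instrument-facing interfaces use the
#' conventional lab units (mm, um, nm, mbar, us, mJ). Beam and spot widths
#' are quoted as FWHM (full width at half maximum) everywhere; the
#' `fwhm_to_sigma()` / `sigma_to_fwhm()` pair is the single place where the
#' Gaussian conversion factor lives.
NULL

#' @rdname units
#' @param p_mbar pressure in millibar
#' @export
mbar_to_pa <- function(p_mbar) p_mbar * 100

#' @rdname units
#' @param p_pa pressure in pascal
#' @export
pa_to_mbar <- function(p_pa) p_pa / 100

#' @rdname units
#' @param x_um length in micrometre
#' @export
um_to_m <- function(x_um) x_um * 1e-6

#' @rdname units
#' @param x_m length in metre
#' @export
m_to_um <- function(x_m) x_m * 1e6

#' @rdname units
#' @param x_mm length in millimetre
#' @export
mm_to_m <- function(x_mm) x_mm * 1e-3

#' @rdname units
#' @param x_nm length in nanometre
#' @export
nm_to_m <- function(x_nm) x_nm * 1e-9

#' @rdname units
#' @param t_us time in microsecond
#' @export
us_to_s <- function(t_us) t_us * 1e-6

#' @rdname units
#' @param fwhm full width at half maximum of a Gaussian
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' @rdname units
#' @param sigma standard deviation of a Gaussian
#' @export
sigma_to_fwhm <- function(sigma) sigma * 2 * sqrt(2 * log(2))

# molar gas constant, J/(mol K)
.R_GAS <- 8.31446261815324
# Boltzmann constant, J/K
.K_BOLTZ <- 1.380649e-23
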