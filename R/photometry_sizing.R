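#' Normalize brightness to center illumination and unit pulse energy
#'
#' Divides the integrated brightness by the relative illumination at the
#' particle position and by the pulse energy, giving photons per mJ at the
#' beam center. Records in the dim outskirts of the illumination (relative
#' intensity below the floor) are flagged unsizable rather than amplified.
#'
#' @param brightness integrated photons
#' @param position `(x, y)` object um (vector or 2-column matrix)
#' @param profile an [illumination_profile()]
#' @param pulse_energy mJ
#' @param floor minimum usable relative illumination
#' @return list with `normalized` (photons/mJ; NA where unsizable) and
#'   `unsizable` (logical)
#' @export
correct_illumination <- function(brightness, position, profile, pulse_energy,
                                 floor = 0.1) {
  rel <- illumination_at(profile, position)
  bad <- rel < floor
  norm <- brightness / (rel * pulse_energy)
  norm[bad] <- NA_real_
  list(normalized = norm, unsizable = bad)
}

#' Fit the Rayleigh brightness-diameter calibration
#'
#' Least-squares fit of the sixth-root of the normalized intensity against
#' diameter, as a line through the origin: `I^(1/6) = k^(1/6) d`. A
#' free-exponent power-law fit (`log I = log a + e log d`) is stored as a
#' diagnostic; on ideal Rayleigh data it returns an exponent of 6.
#'
#' @param standards data.frame with columns `diameter` (nm) and `intensity`
#'   (mean normalized brightness, photons/mJ); one row per size standard
#' @param sizing_window `(min, max)` diameter range (nm) within which the
#'   instrument sizes reliably; stored on the calibration
#' @return object of class `rayleigh_calibration`: `k`
#'   (photons/(nm^6 mJ)), `free_exponent`, `free_amplitude`,
#'   `sizing_window` (nm)
#' @export
fit_calibration <- function(standards, sizing_window = c(40, 125)) {
  stopifnot(nrow(standards) >= 2)
  d <- standards$diameter; I <- standards$intensity
  if (any(I <= 0)) stop("non-positive intensities")
  if (any(d <= 0)) stop("non-positive diameters")
  s <- I^(1 / 6)
  slope <- sum(d * s) / sum(d^2)       # line through origin in 6th-root space
  k <- slope^6
  fe <- stats::lm(log(I) ~ log(d))
  structure(list(k = k,
                 free_exponent = unname(stats::coef(fe)[2]),
                 free_amplitude = exp(unname(stats::coef(fe)[1])),
                 sizing_window = sizing_window),
            class = "rayleigh_calibration")
}

#' Estimate particle diameter from normalized brightness
#'
#' Inverts the Rayleigh law, `d = (I/k)^(1/6)`. Records are unsizable
#' (NA) when saturated, when the brightness is non-positive, or when the
#' estimate falls outside the sizing window of the calibration (the
#' instrument's linear range).
#'
#' @param normalized_brightness photons/mJ (vector)
#' @param calibration a `rayleigh_calibration` from [fit_calibration()]
#' @param saturated logical vector (recycled)
#' @return numeric vector of diameters, nm; NA where unsizable
#' @export
estimate_diameter <- function(normalized_brightness, calibration,
                              saturated = FALSE) {
  saturated <- rep_len(saturated, length(normalized_brightness))
  d <- rep(NA_real_, length(normalized_brightness))
  ok <- !saturated & !is.na(normalized_brightness) &
        normalized_brightness > 0
  d[ok] <- (normalized_brightness[ok] / calibration$k)^(1 / 6)
  w <- calibration$sizing_window
  d[!is.na(d) & (d < w[1] | d > w[2])] <- NA_real_
  d
}

#' Mode of a diameter distribution
#'
#' Kernel-density mode used as the monomer diameter when it is not supplied.
#'
#' @param diameters nm, NA dropped
#' @return modal diameter, nm
#' @export
diameter_mode <- function(diameters) {
  d <- diameters[!is.na(diameters)]
  if (length(d) == 0) stop("no sizable records")
  if (length(d) == 1) return(d)
  dens <- stats::density(d)
  dens$x[which.max(dens$y)]
}

#' Flag particle clusters by oversize diameter
#'
#' Droplets occupied by more than one particle dry into clusters whose
#' effective diameter exceeds the monomer's (a dimer is 2^(1/3) = 1.26 times
#' larger). Records with an estimated diameter above
#' `cutoff_factor * monomer diameter` are flagged as clusters and excluded
#' from beam statistics. The default cutoff 1.15 sits midway between the
#' monomer (1.0) and the dimer (1.26).
#'
#' @param diameters estimated diameters, nm (NA allowed)
#' @param monomer_mode monomer diameter, nm; estimated as the
#'   [diameter_mode()] of the data when NULL
#' @param cutoff_factor multiple of the monomer diameter above which a
#'   record is a cluster
#' @return logical vector, TRUE where flagged as a cluster (FALSE for NA
#'   diameters)
#' @export
flag_clusters <- function(diameters, monomer_mode = NULL,
                          cutoff_factor = 1.15) {
  if (is.null(monomer_mode)) monomer_mode <- diameter_mode(diameters)
  stopifnot(monomer_mode > 0, cutoff_factor > 1)
  !is.na(diameters) & diameters > cutoff_factor * monomer_mode
}
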