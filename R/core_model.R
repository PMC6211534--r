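#' Camera model
#'
#' Container for the sensor and optics parameters that govern photometry.
#' Defaults describe a 2048 x 2048 scientific CMOS camera behind a 2x
#' objective: quantum efficiency 0.8, saturation at about 30700 photons,
#' background of 0.12 photons per pixel per mJ of laser pulse energy,
#' dark-noise fluctuations of 1.3 photons per pixel, and an object-plane
#' pixel scale of 1.14 um per pixel.
#'
#' @param n_pixels_x,n_pixels_y sensor size in pixels (columns, rows)
#' @param pixel_pitch physical pixel pitch on the sensor, um
#' @param quantum_efficiency fraction of photons detected, in (0, 1]
#' @param saturation_level photon count at which a pixel saturates
#' @param dark_noise_sigma Gaussian dark-noise standard deviation,
#'   photons/pixel
#' @param background_rate mean stray-light background, photons/pixel/mJ
#' @param pixel_scale_object object-plane size of one pixel, um/pixel
#' @param reference_pixel (row, col) pixel mapped to the object-plane origin;
#'   0-based, defaults to the frame center
#' @return an object of class `camera_model`
#' @export
camera_model <- function(n_pixels_x = 2048L, n_pixels_y = 2048L,
                         pixel_pitch = 6.5,
                         quantum_efficiency = 0.8,
                         saturation_level = 30700,
                         dark_noise_sigma = 1.3,
                         background_rate = 0.12,
                         pixel_scale_object = 1.14,
                         reference_pixel = NULL) {
  stopifnot(n_pixels_x >= 1, n_pixels_y >= 1, pixel_pitch > 0,
            quantum_efficiency > 0, quantum_efficiency <= 1,
            saturation_level > dark_noise_sigma,
            dark_noise_sigma >= 0, background_rate >= 0,
            pixel_scale_object > 0)
  if (is.null(reference_pixel)) {
    reference_pixel <- c((n_pixels_y - 1) / 2, (n_pixels_x - 1) / 2)
  }
  structure(list(
    n_pixels_x = as.integer(n_pixels_x),
    n_pixels_y = as.integer(n_pixels_y),
    pixel_pitch = pixel_pitch,
    quantum_efficiency = quantum_efficiency,
    saturation_level = saturation_level,
    dark_noise_sigma = dark_noise_sigma,
    background_rate = background_rate,
    pixel_scale_object = pixel_scale_object,
    reference_pixel = as.numeric(reference_pixel)
  ), class = "camera_model")
}

#' Laser model
#'
#' Illumination parameters of the double-pulsed laser. The beam axis lies in
#' the horizontal plane at 25 degrees to the microscope axis; this angle is
#' carried as metadata only, no parallax correction is applied since the
#' dominant (vertical) velocity component is perpendicular to both axes.
#'
#' @param wavelength nm
#' @param pulse_energy per-pulse energy, mJ (recycled to two pulses)
#' @param pulse_delay inter-pulse delay, us (must be > 0 for dual-pulse use)
#' @param spot_fwhm lateral extent (FWHM) of the laser spot, mm
#' @param beam_axis_angle angle between laser and microscope axes, degrees
#' @return an object of class `laser_model`
#' @export
laser_model <- function(wavelength = 532, pulse_energy = 50,
                        pulse_delay = 0.5, spot_fwhm = 0.5,
                        beam_axis_angle = 25) {
  stopifnot(wavelength > 0, all(pulse_energy > 0), spot_fwhm > 0,
            is.na(pulse_delay) || pulse_delay > 0)
  structure(list(
    wavelength = wavelength,
    pulse_energy = pulse_energy,
    pulse_delay = pulse_delay,
    spot_fwhm = spot_fwhm,
    beam_axis_angle = beam_axis_angle
  ), class = "laser_model")
}

#' Microscope frame
#'
#' One camera exposure (possibly double-flash) plus its acquisition metadata.
#' Pixel values are photon counts; matrix rows run down the image (the
#' particle-beam axis points down, i.e. towards increasing row index).
#'
#' @param pixels numeric matrix of photon counts, `n_pixels_y` rows by
#'   `n_pixels_x` columns
#' @param camera a [camera_model()]
#' @param laser a [laser_model()]
#' @param injector_distance distance of the field of view from the injector
#'   tip, mm
#' @param entrance_pressure aerodynamic-lens entrance pressure, mbar
#' @param frame_id identifier
#' @return an object of class `aero_frame`
#' @export
aero_frame <- function(pixels, camera, laser,
                       injector_distance = NA_real_,
                       entrance_pressure = NA_real_,
                       frame_id = 1L) {
  structure(list(
    pixels = pixels, camera = camera, laser = laser,
    injector_distance = injector_distance,
    entrance_pressure = entrance_pressure,
    frame_id = frame_id
  ), class = "aero_frame")
}

#' Validate a frame against its camera model
#'
#' Asserts the frame invariants (dimensions match the camera, pixel values
#' within `[0, saturation_level]`) without modifying any pixel, and reports
#' the number of saturated pixels.
#'
#' @param frame an [aero_frame()]
#' @return the frame, with an attribute `n_saturated` giving the count of
#'   pixels at or above the saturation level
#' @export
validate_frame <- function(frame) {
  stopifnot(inherits(frame, "aero_frame"))
  cam <- frame$camera
  px <- frame$pixels
  if (!is.matrix(px) || nrow(px) != cam$n_pixels_y || ncol(px) != cam$n_pixels_x)
    stop("frame pixel dimensions do not match the camera model")
  if (anyNA(px)) stop("frame contains NA pixels")
  if (any(px < 0)) stop("frame contains negative pixel values")
  if (any(px > cam$saturation_level))
    stop("frame contains pixel values above the saturation level")
  attr(frame, "n_saturated") <- sum(px >= cam$saturation_level)
  frame
}

#' Convert pixel centroids to object-plane coordinates
#'
#' Linear scaling by the object-plane pixel scale about a configured
#' reference pixel. Pixel coordinates are 0-based `(row, col)` with the
#' origin at the top-left pixel center; object coordinates are `(x, y)` um
#' with x along image columns and y along image rows, i.e. down the particle
#' beam.
#'
#' @param centroid numeric vector `(row, col)` or a 2-column matrix of
#'   centroids (pixels, 0-based)
#' @param camera a [camera_model()]
#' @return `(x, y)` in um (vector or 2-column matrix, matching the input)
#' @export
pixels_to_object_coords <- function(centroid, camera) {
  m <- if (is.matrix(centroid)) centroid else matrix(centroid, ncol = 2)
  if (any(m[, 1] < 0 | m[, 1] > camera$n_pixels_y - 1 |
          m[, 2] < 0 | m[, 2] > camera$n_pixels_x - 1))
    stop("centroid outside frame bounds")
  ref <- camera$reference_pixel
  out <- cbind(x = (m[, 2] - ref[2]) * camera$pixel_scale_object,
               y = (m[, 1] - ref[1]) * camera$pixel_scale_object)
  if (is.matrix(centroid)) out else drop(out)
}

#' Convert object-plane coordinates to pixel coordinates
#'
#' Inverse of [pixels_to_object_coords()]; the round trip is the identity to
#' floating precision. Positions outside the sensor are returned as-is (the
#' renderer uses them to decide visibility).
#'
#' @param xy numeric vector `(x, y)` um or a 2-column matrix
#' @param camera a [camera_model()]
#' @return `(row, col)` pixel coordinates (0-based), vector or matrix
#' @export
object_coords_to_pixels <- function(xy, camera) {
  m <- if (is.matrix(xy)) xy else matrix(xy, ncol = 2)
  ref <- camera$reference_pixel
  out <- cbind(row = m[, 2] / camera$pixel_scale_object + ref[1],
               col = m[, 1] / camera$pixel_scale_object + ref[2])
  if (is.matrix(xy)) out else drop(out)
}

#' Ground-truth particle description (synthetic scenes)
#'
#' @param diameter monomer-equivalent particle diameter, nm; for a cluster of
#'   `n_monomers` spheres the effective diameter is
#'   `diameter * n_monomers^(1/3)` (volume conservation)
#' @param position `(x, y)` object-plane position at the first flash, um
#' @param velocity `(vx, vy)` m/s
#' @param mass_density particle mass density, kg/m^3 (polystyrene default)
#' @param n_monomers number of monomers in the (possibly clustered) particle
#' @return a one-row data.frame; rbind several to build a scene
#' @export
particle <- function(diameter, position = c(0, 0), velocity = c(0, 0),
                     mass_density = 1050, n_monomers = 1L) {
  stopifnot(diameter > 0, n_monomers >= 1)
  data.frame(diameter = diameter,
             x = position[1], y = position[2],
             vx = velocity[1], vy = velocity[2],
             mass_density = mass_density,
             n_monomers = as.integer(n_monomers))
}

#' Effective diameter of an n-monomer cluster
#'
#' Volume-conserving coalescence: `d_monomer * n^(1/3)`.
#'
#' @param d_monomer monomer diameter, nm
#' @param n_monomers monomer count (>= 1)
#' @return effective cluster diameter, nm
#' @export
cluster_diameter <- function(d_monomer, n_monomers) {
  stopifnot(all(d_monomer > 0), all(n_monomers >= 1))
  d_monomer * n_monomers^(1 / 3)
}
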