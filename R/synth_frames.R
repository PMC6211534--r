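#' Gaussian illumination profile
#'
#' Relative illumination intensity across the object plane, modeling the
#' focused laser spot. Isotropic Gaussian with unit peak; the relative
#' intensity is 0.5 at a distance of FWHM/2 from the center.
#'
#' @param fwhm full width at half maximum of the spot, mm
#' @param center `(x, y)` object-plane center of the spot, um
#' @return an object of class `illumination_profile`
#' @export
illumination_profile <- function(fwhm = 0.5, center = c(0, 0)) {
  stopifnot(fwhm > 0)
  structure(list(fwhm = fwhm, center = as.numeric(center)),
            class = "illumination_profile")
}

#' Relative illumination at object-plane positions
#'
#' @param profile an [illumination_profile()]
#' @param xy `(x, y)` um, vector or 2-column matrix
#' @return relative intensity in (0, 1]
#' @export
illumination_at <- function(profile, xy) {
  m <- if (is.matrix(xy)) xy else matrix(xy, ncol = 2)
  fwhm_um <- profile$fwhm * 1000
  r2 <- (m[, 1] - profile$center[1])^2 + (m[, 2] - profile$center[2])^2
  exp(-4 * log(2) * r2 / fwhm_um^2)
}

#' Default Rayleigh brightness constant
#'
#' Calibration constant k in photons/(nm^6 mJ) chosen such that a 40 nm
#' polystyrene sphere at the illumination center yields 157 detected photons
#' for a 50 mJ pulse, the benchmark sensitivity of the instrument.
#'
#' @return k, photons/(nm^6 mJ)
#' @export
default_rayleigh_k <- function() 157 / (40^6 * 50)

#' Expected integrated photons of a Rayleigh scatterer
#'
#' Rayleigh scattering: the detected signal scales with the sixth power of
#' the particle diameter, linearly with pulse energy and with the local
#' relative illumination. Valid for particles small compared with the
#' wavelength; a warning is issued above 200 nm where the Rayleigh
#' approximation degrades into the Mie regime.
#'
#' @param d_p particle diameter, nm
#' @param k calibration constant, photons/(nm^6 mJ)
#' @param pulse_energy mJ
#' @param illumination relative illumination intensity in (0, 1]
#' @return expected integrated photons
#' @export
expected_spot_photons <- function(d_p, k = default_rayleigh_k(),
                                  pulse_energy = 50, illumination = 1) {
  if (any(d_p <= 0) || k <= 0 || any(pulse_energy <= 0) ||
      any(illumination <= 0))
    stop("d_p, k, pulse_energy and illumination must be positive")
  if (any(d_p > 200))
    warning("diameter above 200 nm: outside the Rayleigh regime, d^6 scaling unreliable")
  k * d_p^6 * pulse_energy * illumination
}

#' Synthetic scene specification
#'
#' Everything needed to render a double-exposure frame: the ground-truth
#' particles, photometric calibration, point-spread function, pulse pair,
#' ghost (back-reflection) model and random seed.
#'
#' @param particles data.frame of [particle()] rows
#' @param k Rayleigh calibration constant, photons/(nm^6 mJ)
#' @param psf_sigma Gaussian PSF standard deviation, pixels
#' @param pulse_pair energies of the two flashes, mJ (one value = single
#'   flash)
#' @param pulse_delay inter-pulse delay, us
#' @param illumination an [illumination_profile()]
#' @param ghost_offset `(drow, dcol)` constant pixel displacement of the
#'   back-reflection ghost relative to its parent spot, or NULL for no ghosts
#' @param ghost_intensity_fraction ghost brightness as a fraction of the
#'   parent spot, in [0, 1)
#' @param cluster_occupancy_mean Poisson mean of droplet occupancy used by
#'   [sample_cluster_sizes()] (stored for provenance; clustering is applied
#'   when building the particle table)
#' @param seed integer seed making the rendering deterministic
#' @return an object of class `scene_spec`
#' @export
scene_spec <- function(particles, k = default_rayleigh_k(), psf_sigma = 2,
                       pulse_pair = c(50, 50), pulse_delay = 0.5,
                       illumination = illumination_profile(),
                       ghost_offset = NULL, ghost_intensity_fraction = 0.1,
                       cluster_occupancy_mean = NA_real_, seed = NULL) {
  stopifnot(k > 0, psf_sigma > 0,
            ghost_intensity_fraction >= 0, ghost_intensity_fraction < 1)
  structure(list(
    particles = particles, k = k, psf_sigma = psf_sigma,
    pulse_pair = pulse_pair, pulse_delay = pulse_delay,
    illumination = illumination,
    ghost_offset = ghost_offset,
    ghost_intensity_fraction = ghost_intensity_fraction,
    cluster_occupancy_mean = cluster_occupancy_mean,
    seed = seed
  ), class = "scene_spec")
}

# Add one pixel-integrated Gaussian spot (total = photons) to `img` in place.
# row/col are 0-based pixel coordinates of the spot center.
.add_spot <- function(img, row, col, sigma, photons) {
  nr <- nrow(img); nc <- ncol(img)
  half <- ceiling(6 * sigma) + 1
  r0 <- max(0, floor(row - half)); r1 <- min(nr - 1, ceiling(row + half))
  c0 <- max(0, floor(col - half)); c1 <- min(nc - 1, ceiling(col + half))
  if (r0 > r1 || c0 > c1) return(img)
  rr <- r0:r1; cc <- c0:c1
  wr <- stats::pnorm(rr + 0.5, row, sigma) - stats::pnorm(rr - 0.5, row, sigma)
  wc <- stats::pnorm(cc + 0.5, col, sigma) - stats::pnorm(cc - 0.5, col, sigma)
  img[rr + 1, cc + 1] <- img[rr + 1, cc + 1] + photons * (wr %o% wc)
  img
}

#' Render a synthetic double-exposure frame
#'
#' Forward model of the instrument. For each particle and each flash a
#' pixel-integrated Gaussian spot is placed at the particle's position at
#' that flash time (the position advances by `velocity * pulse_delay`
#' between flashes), with total photons given by [expected_spot_photons()]
#' at the local illumination. Back-reflection ghosts are added at a constant
#' pixel offset with a fixed intensity fraction (only when the ghost's peak
#' pixel would exceed one dark-noise sigma). Stray-light background is
#' Poisson with mean `background_rate * total pulse energy`; dark noise is
#' additive Gaussian. Pixels are clamped at zero and clipped at the
#' saturation level.
#'
#' @param scene a [scene_spec()]
#' @param camera a [camera_model()]
#' @param injector_distance,entrance_pressure,frame_id frame metadata
#' @param shot_noise if FALSE, the spot and background expectations are
#'   rendered without Poisson sampling (used for photometric checks)
#' @param dark_noise if FALSE, no Gaussian dark noise is added
#' @return list with `frame` (an [aero_frame()]) and `truth` (data.frame,
#'   one row per particle per flash: particle id, flash, diameter,
#'   n_monomers, object position, pixel position, velocity, expected
#'   photons, visibility flag)
#' @export
render_frame <- function(scene, camera,
                         injector_distance = NA_real_,
                         entrance_pressure = NA_real_,
                         frame_id = 1L,
                         shot_noise = TRUE, dark_noise = TRUE) {
  if (!is.null(scene$seed)) set.seed(scene$seed)
  nr <- camera$n_pixels_y; nc <- camera$n_pixels_x
  img <- matrix(0, nr, nc)
  energies <- scene$pulse_pair
  n_flash <- length(energies)
  pts <- scene$particles
  truth <- NULL
  if (!is.null(pts) && nrow(pts) > 0) {
    rows <- vector("list", nrow(pts) * n_flash)
    for (i in seq_len(nrow(pts))) {
      d_eff <- cluster_diameter(pts$diameter[i], pts$n_monomers[i])
      for (f in seq_len(n_flash)) {
        dt <- (f - 1) * scene$pulse_delay  # us; m/s * us = um
        xy <- c(pts$x[i] + pts$vx[i] * dt, pts$y[i] + pts$vy[i] * dt)
        rel <- illumination_at(scene$illumination, xy)
        photons <- expected_spot_photons(d_eff, scene$k, energies[f], rel)
        pix <- object_coords_to_pixels(xy, camera)
        visible <- pix[1] >= 0 && pix[1] <= nr - 1 &&
                   pix[2] >= 0 && pix[2] <= nc - 1
        img <- .add_spot(img, pix[1], pix[2], scene$psf_sigma, photons)
        if (!is.null(scene$ghost_offset) && scene$ghost_intensity_fraction > 0) {
          gp <- scene$ghost_intensity_fraction * photons
          peak <- gp / (2 * pi * scene$psf_sigma^2)
          if (peak > camera$dark_noise_sigma)
            img <- .add_spot(img, pix[1] + scene$ghost_offset[1],
                             pix[2] + scene$ghost_offset[2],
                             scene$psf_sigma, gp)
        }
        rows[[(i - 1) * n_flash + f]] <- data.frame(
          particle = i, flash = f, diameter = d_eff,
          n_monomers = pts$n_monomers[i],
          x = xy[1], y = xy[2], row = pix[1], col = pix[2],
          vx = pts$vx[i], vy = pts$vy[i],
          photons = photons, visible = visible)
      }
    }
    truth <- do.call(rbind, rows)
  } else {
    truth <- data.frame(particle = integer(), flash = integer(),
                        diameter = numeric(), n_monomers = integer(),
                        x = numeric(), y = numeric(),
                        row = numeric(), col = numeric(),
                        vx = numeric(), vy = numeric(),
                        photons = numeric(), visible = logical())
  }
  bg_mean <- camera$background_rate * sum(energies)
  if (shot_noise) {
    img <- matrix(stats::rpois(nr * nc, img + bg_mean), nr, nc)
  } else {
    img <- img + bg_mean
  }
  if (dark_noise && camera$dark_noise_sigma > 0) {
    img <- img + matrix(stats::rnorm(nr * nc, 0, camera$dark_noise_sigma), nr, nc)
  }
  img[img < 0] <- 0
  img[img > camera$saturation_level] <- camera$saturation_level
  laser <- laser_model(pulse_energy = energies,
                       pulse_delay = if (n_flash > 1) scene$pulse_delay else NA_real_,
                       spot_fwhm = scene$illumination$fwhm)
  fr <- aero_frame(img, camera, laser, injector_distance, entrance_pressure,
                   frame_id)
  if (!is.null(truth) && nrow(truth) > 0) truth$frame_id <- frame_id
  list(frame = fr, truth = truth)
}

#' Sample droplet-occupancy cluster sizes
#'
#' Aerosolized droplets contain a Poisson-distributed number of particles;
#' droplets observed as particles contain at least one, so monomer counts
#' follow a zero-truncated Poisson distribution. Dried clusters coalesce
#' into a single effective sphere of diameter `d_monomer * n^(1/3)`.
#'
#' @param n number of draws
#' @param occupancy_mean Poisson mean occupancy of the droplets (> 0)
#' @param seed optional integer seed
#' @return integer vector of monomer counts, all >= 1
#' @export
sample_cluster_sizes <- function(n, occupancy_mean, seed = NULL) {
  stopifnot(occupancy_mean > 0, n >= 0)
  if (!is.null(seed)) set.seed(seed)
  # inverse-CDF draw from the zero-truncated Poisson
  u <- stats::runif(n)
  p0 <- stats::ppois(0, occupancy_mean)
  stats::qpois(p0 + u * (1 - p0), occupancy_mean)
}

#' Generate a synthetic pressure/distance scan
#'
#' Forward model for beam-characterization recovery tests. For each entrance
#' pressure the particle beam is a Gaussian beam whose FWHM waist, focus
#' distance and divergence follow power laws of the pressure; transverse
#' particle positions at each injector distance are drawn from the Gaussian
#' envelope width at that distance, and axial velocities come from the
#' free-jet drag model (or a user-supplied function).
#'
#' @param pressures entrance pressures, mbar
#' @param distances injector distances, mm
#' @param waist_fwhm_ref FWHM waist at `pressure_ref`, um
#' @param focus_distance_ref focus distance at `pressure_ref`, mm
#' @param divergence_ref far-field FWHM half-angle at `pressure_ref`, mrad
#' @param pressure_ref reference pressure, mbar
#' @param waist_exponent,focus_exponent,divergence_exponent power-law
#'   exponents of the three beam parameters vs pressure
#' @param n_per_cell number of particles drawn per (pressure, distance) cell
#' @param diameter particle diameter, nm
#' @param velocity_fn function(pressure_mbar, distance_mm, diameter_nm) ->
#'   axial speed m/s; default uses [jet_terminal_velocity()]
#' @param seed integer seed
#' @return data.frame of ground truth: pressure, distance, x (transverse,
#'   um), vy (m/s), diameter, plus the generating beam parameters as
#'   attribute `beam_truth`
#' @export
generate_pressure_scan <- function(pressures, distances,
                                   waist_fwhm_ref = 40,
                                   focus_distance_ref = 3,
                                   divergence_ref = 20,
                                   pressure_ref = 1,
                                   waist_exponent = -1.5,
                                   focus_exponent = -0.5,
                                   divergence_exponent = -1,
                                   n_per_cell = 200,
                                   diameter = 100,
                                   velocity_fn = NULL,
                                   seed = NULL) {
  if (length(pressures) < 1 || length(distances) < 1)
    stop("pressures and distances must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(velocity_fn)) {
    vcache <- new.env()
    velocity_fn <- function(p, z, d) {
      key <- paste(p, d)
      if (is.null(vcache[[key]]))
        vcache[[key]] <- jet_terminal_velocity(p, d)
      vcache[[key]]
    }
  }
  beam_truth <- data.frame(
    pressure = pressures,
    waist_fwhm = waist_fwhm_ref * (pressures / pressure_ref)^waist_exponent,
    focus_distance = focus_distance_ref * (pressures / pressure_ref)^focus_exponent,
    divergence = divergence_ref * (pressures / pressure_ref)^divergence_exponent)
  out <- list()
  for (i in seq_along(pressures)) {
    w0 <- beam_truth$waist_fwhm[i]           # um FWHM
    z0 <- beam_truth$focus_distance[i]       # mm
    th <- beam_truth$divergence[i]           # mrad = um/mm, FWHM half-angle
    zR <- w0 / (2 * th)                      # mm
    for (z in distances) {
      w <- w0 * sqrt(1 + ((z - z0) / zR)^2)  # FWHM, um
      x <- stats::rnorm(n_per_cell, 0, fwhm_to_sigma(w))
      v <- velocity_fn(pressures[i], z, diameter)
      out[[length(out) + 1]] <- data.frame(
        pressure = pressures[i], distance = z, x = x,
        vy = v, diameter = diameter)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "beam_truth") <- beam_truth
  res
}
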