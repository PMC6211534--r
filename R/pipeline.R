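#' Build a randomized synthetic scene
#'
#' Draws a Poisson number of particles, transverse positions from the
#' particle-beam Gaussian, axial positions uniform over the field of view,
#' droplet-occupancy cluster sizes, and a common axial velocity with
#' multiplicative jitter. Used by the simulation stage of the pipeline and
#' by the test suite.
#'
#' @param camera a [camera_model()]
#' @param mean_particles Poisson mean particle count per frame
#' @param diameter monomer diameter, nm
#' @param beam_sigma transverse (x) Gaussian sigma of the particle beam, um
#' @param speed mean axial speed, m/s
#' @param speed_jitter multiplicative sd of the speed
#' @param cluster_occupancy_mean droplet occupancy Poisson mean; NA for
#'   monomers only
#' @param margin object-plane margin (um) kept free at the top so both
#'   flash images stay in frame
#' @param seed optional integer seed
#' @return data.frame of [particle()] rows
#' @export
random_scene <- function(camera, mean_particles = 3, diameter = 100,
                         beam_sigma = 50, speed = 30, speed_jitter = 0.05,
                         cluster_occupancy_mean = NA_real_, margin = 100,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, mean_particles)
  half_h <- (camera$n_pixels_y - 1) / 2 * camera$pixel_scale_object
  half_w <- (camera$n_pixels_x - 1) / 2 * camera$pixel_scale_object
  if (n == 0)
    return(particle(diameter)[0, ])
  x <- pmin(pmax(stats::rnorm(n, 0, beam_sigma), -half_w), half_w)
  y <- stats::runif(n, -half_h + margin / 2, half_h - margin)
  nm <- if (is.na(cluster_occupancy_mean)) rep(1L, n)
        else sample_cluster_sizes(n, cluster_occupancy_mean)
  v <- speed * (1 + stats::rnorm(n, 0, speed_jitter))
  do.call(rbind, lapply(seq_len(n), function(i)
    particle(diameter, c(x[i], y[i]), c(0, v[i]), n_monomers = nm[i])))
}

#' Run the full simulation-backed analysis pipeline
#'
#' Executes simulate -> detect -> track -> size -> beamfit with per-stage
#' artifacts on disk, deterministic under the configured seed. Stage
#' summaries (counts detected / paired / sized / excluded) are logged to
#' stderr and returned in the report.
#'
#' @param config named list (see Details) or a path readable by
#'   [read_config()]
#' @param out_dir output directory for stage artifacts
#' @param verbose log per-frame detail
#' @details Required config entries: `seed`; `n_frames`; `scene` (arguments
#'   of [random_scene()]); `pulse_delay` (us, required when tracking);
#'   `pulse_energies` (mJ, two values); `detection` (arguments of
#'   [detection_config()]); optional `camera` and `illumination` argument
#'   lists, `calibration_k`, `sizing_window`, `axial_length` (um) for the
#'   density stage.
#' @return report list: per-stage counts, fitted profile/density, artifact
#'   paths
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  if (is.character(config)) config <- read_config(config)
  for (key in c("seed", "n_frames", "scene", "detection"))
    if (is.null(config[[key]]))
      stop("config is missing required entry '", key, "'")
  if (is.null(config$pulse_delay))
    stop("config is missing 'pulse_delay' (us), required for tracking")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cam <- do.call(camera_model, as.list(config$camera))
  illum <- do.call(illumination_profile, as.list(config$illumination))
  energies <- config$pulse_energies %||% c(50, 50)
  k <- config$calibration_k %||% default_rayleigh_k()
  log_msg <- function(...) message("[aerotrack] ", ...)

  # --- simulate -------------------------------------------------------
  set.seed(config$seed)
  frames <- vector("list", config$n_frames)
  truths <- vector("list", config$n_frames)
  for (i in seq_len(config$n_frames)) {
    pts <- do.call(random_scene, c(list(camera = cam), config$scene))
    sc <- scene_spec(pts, k = k,
                     psf_sigma = config$psf_sigma %||% 2,
                     pulse_pair = energies,
                     pulse_delay = config$pulse_delay,
                     illumination = illum,
                     ghost_offset = config$ghost_offset,
                     ghost_intensity_fraction =
                       config$ghost_intensity_fraction %||% 0)
    r <- render_frame(sc, cam, frame_id = i)
    frames[[i]] <- r$frame
    truths[[i]] <- r$truth
    if (verbose) log_msg("frame ", i, ": ", nrow(r$truth) / 2, " particles")
  }
  truth <- do.call(rbind, truths)
  frames_path <- file.path(out_dir, "frames.tiff")
  write_frames_tiff(frames, frames_path)
  write_table_csv(truth, file.path(out_dir, "truth.csv"))
  log_msg("simulated ", config$n_frames, " frames, ",
          sum(truth$flash == 1), " particles")

  # --- detect ---------------------------------------------------------
  det <- do.call(detection_config, as.list(config$detection))
  peaks <- do.call(rbind, lapply(frames, detect_peaks, config = det))
  write_table_csv(peaks, file.path(out_dir, "peaks.csv"))
  log_msg("detected ", nrow(peaks), " peaks (",
          sum(peaks$ghost), " ghosts, ", sum(peaks$proximity_excluded),
          " proximity-excluded)")

  # --- track ----------------------------------------------------------
  usable <- peaks[!peaks$ghost & !peaks$proximity_excluded, ]
  tracks <- do.call(rbind, lapply(split(usable, usable$frame_id),
                                  pair_flashes,
                                  pulse_delay = config$pulse_delay))
  write_table_csv(tracks, file.path(out_dir, "tracks.csv"))
  n_pairs <- sum(tracks$paired & !tracks$is_second)
  log_msg("paired ", n_pairs, " tracks")

  # --- size -----------------------------------------------------------
  # one spot = one flash in a moving double-flash scene, so the per-pulse
  # calibration constant applies with the mean single-pulse energy
  cor <- correct_illumination(tracks$brightness,
                              as.matrix(tracks[, c("x", "y")]),
                              illum, mean(energies))
  cal <- structure(list(k = k,
                        sizing_window = config$sizing_window %||% c(40, 125)),
                   class = "rayleigh_calibration")
  tracks$diameter <- estimate_diameter(cor$normalized, cal,
                                       saturated = tracks$saturated)
  tracks$cluster <- tryCatch(flag_clusters(tracks$diameter),
                             error = function(e) rep(FALSE, nrow(tracks)))
  write_table_csv(tracks, file.path(out_dir, "sized.csv"))
  log_msg("sized ", sum(!is.na(tracks$diameter)), " of ", nrow(tracks),
          " records, ", sum(tracks$cluster), " flagged as clusters")

  # --- beamfit --------------------------------------------------------
  sel <- tracks$paired & !tracks$is_second & !tracks$cluster
  report_profile <- NULL
  density <- NULL
  if (sum(sel) >= 50) {
    prof <- transverse_profile(tracks$x[sel])
    counts <- as.numeric(table(factor(tracks$frame_id[sel],
                                      levels = seq_len(config$n_frames))))
    h_um <- cam$n_pixels_y * cam$pixel_scale_object
    w_um <- cam$n_pixels_x * cam$pixel_scale_object
    density <- areal_density(counts, h_um * w_um, profile = prof,
                             axial_length = config$axial_length %||% h_um)
    report_profile <- prof
    jsonlite::write_json(
      list(profile = prof[c("center", "fwhm", "sigma", "n")],
           density = density),
      file.path(out_dir, "beam.json"), auto_unbox = TRUE, digits = NA)
    log_msg("beam FWHM ", signif(prof$fwhm, 4), " um, mean density ",
            signif(density$mean_density, 4), " /um^2")
  } else {
    log_msg("too few tracks for a beam profile (", sum(sel), ")")
  }

  list(n_frames = config$n_frames,
       n_true_particles = sum(truth$flash == 1),
       n_peaks = nrow(peaks),
       n_ghosts = sum(peaks$ghost),
       n_proximity_excluded = sum(peaks$proximity_excluded),
       n_paired = n_pairs,
       n_sized = sum(!is.na(tracks$diameter)),
       n_clusters = sum(tracks$cluster),
       profile = report_profile,
       density = density,
       paths = list(frames = frames_path,
                    truth = file.path(out_dir, "truth.csv"),
                    peaks = file.path(out_dir, "peaks.csv"),
                    tracks = file.path(out_dir, "tracks.csv"),
                    sized = file.path(out_dir, "sized.csv"),
                    beam = file.path(out_dir, "beam.json")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
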