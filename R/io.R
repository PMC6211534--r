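#' Write frames to a 16-bit grayscale TIFF stack
#'
#' Photon counts are stored as 16-bit fractions of the camera saturation
#' level (the native dynamic range of the sensor), one page per frame.
#'
#' @param frames list of [aero_frame()] (or a single frame)
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
write_frames_tiff <- function(frames, path) {
  if (inherits(frames, "aero_frame")) frames <- list(frames)
  imgs <- lapply(frames, function(fr) {
    m <- fr$pixels / fr$camera$saturation_level
    m[m < 0] <- 0
    m[m > 1] <- 1
    m
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read frames from a TIFF stack
#'
#' Inverse of [write_frames_tiff()]: pixel fractions are rescaled to photon
#' counts with the camera's saturation level. Per-frame metadata (injector
#' distance, entrance pressure) comes from the accompanying arguments.
#'
#' @param path TIFF path (single- or multi-page, 16-bit grayscale)
#' @param camera a [camera_model()]
#' @param laser a [laser_model()]
#' @param injector_distance,entrance_pressure recycled over frames
#' @return list of [aero_frame()]
#' @export
read_frames_tiff <- function(path, camera, laser,
                             injector_distance = NA_real_,
                             entrance_pressure = NA_real_) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  n <- length(imgs)
  injector_distance <- rep_len(injector_distance, n)
  entrance_pressure <- rep_len(entrance_pressure, n)
  lapply(seq_len(n), function(i) {
    px <- imgs[[i]]
    if (length(dim(px)) == 3) px <- px[, , 1]
    aero_frame(px * camera$saturation_level, camera, laser,
               injector_distance[i], entrance_pressure[i], frame_id = i)
  })
}

#' Load a pipeline configuration
#'
#' Reads a YAML (or JSON) configuration holding the camera and laser
#' models, per-dataset metadata and stage parameters.
#'
#' @param path file path ending in .yaml/.yml or .json
#' @return named list
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config named list
#' @export
write_config <- function(config, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(config, path)
  invisible(path)
}

#' Write / read a particle table
#'
#' Headered UTF-8 CSV with '.' decimal separator; write-then-read
#' round-trips all values.
#'
#' @param x data.frame
#' @param path CSV path
#' @return `path` (write) or a data.frame (read)
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
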