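#' Detection configuration
#'
#' Parameters of the spot-detection stage. The difference-of-Gaussians
#' (DoG) blur pair acts at the spot scale (defaults 3 and 6 px); the
#' detection threshold is applied to the signed DoG image and must be chosen
#' well above background fluctuations ([suggest_threshold()] helps).
#' Brightness is integrated on the raw image within a 10 px radius; peaks
#' closer together than 21 px are mutually excluded from analysis.
#'
#' @param sigma_small,sigma_large DoG blur sigmas, pixels
#'   (`sigma_small < sigma_large`)
#' @param threshold detection threshold on the DoG image, photons
#' @param integration_radius brightness integration radius, pixels
#' @param min_separation proximity-exclusion distance, pixels (strict
#'   "closer than")
#' @param connectivity pixel connectivity for clustering supra-threshold
#'   pixels, 4 or 8
#' @param ghost_offset `(drow, dcol)` expected back-reflection displacement
#'   in pixels, or "auto" to estimate it from the data, or NULL to skip
#'   ghost filtering
#' @param ghost_tolerance matching tolerance for the ghost offset, pixels
#' @param annulus_subtract subtract the annulus-median background from the
#'   integrated brightness (off by default; the stray-light background is
#'   otherwise included in the integral)
#' @return an object of class `detection_config`
#' @export
detection_config <- function(sigma_small = 3, sigma_large = 6,
                             threshold, integration_radius = 10,
                             min_separation = 21, connectivity = 4,
                             ghost_offset = NULL, ghost_tolerance = 2,
                             annulus_subtract = FALSE) {
  stopifnot(sigma_small > 0, sigma_large > sigma_small,
            threshold > 0, integration_radius > 0, min_separation >= 0,
            connectivity %in% c(4, 8), ghost_tolerance > 0)
  structure(list(sigma_small = sigma_small, sigma_large = sigma_large,
                 threshold = threshold,
                 integration_radius = integration_radius,
                 min_separation = min_separation,
                 connectivity = connectivity,
                 ghost_offset = ghost_offset,
                 ghost_tolerance = ghost_tolerance,
                 annulus_subtract = annulus_subtract),
            class = "detection_config")
}

#' Difference-of-Gaussians filter
#'
#' Subtracts a large-sigma Gaussian blur from a small-sigma blur of the same
#' image, acting as a band-pass that suppresses both pixel noise and the
#' smooth background. Linear in the input; constants map to zero.
#'
#' @param image 2-D numeric matrix
#' @param sigma_small,sigma_large blur standard deviations, pixels
#' @return matrix of the same size
#' @export
dog_filter <- function(image, sigma_small = 3, sigma_large = 6) {
  if (!is.matrix(image)) stop("image must be a 2-D matrix")
  stopifnot(sigma_small > 0, sigma_large > sigma_small)
  b1 <- EBImage::gblur(image, sigma = sigma_small, boundary = "replicate")
  b2 <- EBImage::gblur(image, sigma = sigma_large, boundary = "replicate")
  b1 - b2
}

#' Suggest a detection threshold from a particle-free region
#'
#' Computes mean + `n_sigma` standard deviations of the DoG image over a
#' region assumed free of particles, mimicking the manual threshold choice
#' "well above background fluctuations".
#'
#' @param dog_image DoG-filtered matrix (particle-free, or mostly so)
#' @param n_sigma multiple of the DoG standard deviation above the mean
#' @return suggested threshold, photons
#' @export
suggest_threshold <- function(dog_image, n_sigma = 5) {
  mean(dog_image) + n_sigma * stats::sd(as.numeric(dog_image))
}

# Label connected components among supra-threshold pixels. Works on the
# sparse set of candidate pixels, so cost scales with their number, not the
# frame size. Returns a data.frame row/col (0-based) with a component label.
.label_components <- function(mask_idx, nr, nc, connectivity = 4) {
  if (nrow(mask_idx) == 0)
    return(data.frame(row = integer(), col = integer(), label = integer()))
  key <- mask_idx[, 1] + nr * mask_idx[, 2]    # 0-based linear index
  lookup <- new.env(hash = TRUE, size = nrow(mask_idx))
  for (i in seq_len(nrow(mask_idx))) assign(as.character(key[i]), i, envir = lookup)
  offs <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(rep(-1:1, 3), rep(-1:1, each = 3))[-5, ]
  }
  label <- integer(nrow(mask_idx))
  cur <- 0L
  for (i in seq_len(nrow(mask_idx))) {
    if (label[i] > 0) next
    cur <- cur + 1L
    stack <- i
    label[i] <- cur
    while (length(stack) > 0) {
      j <- stack[length(stack)]; stack <- stack[-length(stack)]
      r <- mask_idx[j, 1]; c <- mask_idx[j, 2]
      for (o in seq_len(nrow(offs))) {
        rn <- r + offs[o, 1]; cn <- c + offs[o, 2]
        if (rn < 0 || rn >= nr || cn < 0 || cn >= nc) next
        nb <- mget(as.character(rn + nr * cn), envir = lookup,
                   ifnotfound = list(NULL))[[1]]
        if (!is.null(nb) && label[nb] == 0) {
          label[nb] <- cur
          stack <- c(stack, nb)
        }
      }
    }
  }
  data.frame(row = mask_idx[, 1], col = mask_idx[, 2], label = label)
}

#' Find candidate peaks as supra-threshold pixel clusters
#'
#' One candidate peak is assigned to each isolated (connected) cluster of
#' pixels whose DoG value exceeds the threshold. The signed DoG image is
#' thresholded (positive lobes).
#'
#' @param dog_image DoG-filtered matrix
#' @param threshold detection threshold (> 0)
#' @param connectivity 4 (default) or 8
#' @return data.frame with columns row, col (0-based pixel coordinates),
#'   value (DoG value) and label (cluster id); zero rows if nothing exceeds
#'   the threshold
#' @export
find_peaks <- function(dog_image, threshold, connectivity = 4) {
  stopifnot(threshold > 0)
  idx <- which(dog_image > threshold, arr.ind = TRUE)
  comp <- .label_components(cbind(idx[, 1] - 1L, idx[, 2] - 1L),
                            nrow(dog_image), ncol(dog_image), connectivity)
  comp$value <- dog_image[cbind(comp$row + 1L, comp$col + 1L)]
  comp
}

#' Intensity-weighted centroid of a pixel cluster
#'
#' Center of mass of the selected pixels, weighted by their (DoG) values.
#'
#' @param cluster data.frame with columns row, col, value (one cluster)
#' @return `(row, col)` centroid, 0-based pixels
#' @export
peak_centroid <- function(cluster) {
  if (nrow(cluster) == 0) stop("empty cluster")
  w <- cluster$value
  tw <- sum(w)
  if (tw <= 0) stop("cluster has non-positive total weight")
  c(row = sum(cluster$row * w) / tw, col = sum(cluster$col * w) / tw)
}

#' Integrated spot brightness
#'
#' Sum of raw pixel values whose centers lie within `radius` pixels of the
#' peak centroid. No background subtraction is applied by default (set
#' `annulus_subtract = TRUE` for annulus-median subtraction). The result is
#' flagged partial when the integration disk extends beyond the frame and
#' saturated when any pixel in the disk reaches the saturation level.
#'
#' @param image raw frame matrix (photon counts)
#' @param centroid `(row, col)` 0-based peak position
#' @param radius integration radius, pixels
#' @param saturation_level optional; pixels at or above it set the
#'   saturated flag
#' @param annulus_subtract subtract the median of an annulus (radius to
#'   2*radius) from every disk pixel
#' @return list with `brightness` (photons), `n_pixels`, `partial`,
#'   `saturated`
#' @export
integrate_brightness <- function(image, centroid, radius = 10,
                                 saturation_level = Inf,
                                 annulus_subtract = FALSE) {
  nr <- nrow(image); nc <- ncol(image)
  if (centroid[1] < 0 || centroid[1] > nr - 1 ||
      centroid[2] < 0 || centroid[2] > nc - 1)
    stop("centroid outside frame")
  r0 <- max(0, floor(centroid[1] - 2 * radius))
  r1 <- min(nr - 1, ceiling(centroid[1] + 2 * radius))
  c0 <- max(0, floor(centroid[2] - 2 * radius))
  c1 <- min(nc - 1, ceiling(centroid[2] + 2 * radius))
  rr <- r0:r1; cc <- c0:c1
  dist2 <- outer((rr - centroid[1])^2, (cc - centroid[2])^2, `+`)
  sub <- image[rr + 1, cc + 1, drop = FALSE]
  disk <- dist2 <= radius^2
  partial <- centroid[1] - radius < 0 || centroid[1] + radius > nr - 1 ||
             centroid[2] - radius < 0 || centroid[2] + radius > nc - 1
  vals <- sub[disk]
  bg <- 0
  if (annulus_subtract) {
    ann <- dist2 > radius^2 & dist2 <= (2 * radius)^2
    if (any(ann)) bg <- stats::median(sub[ann])
  }
  list(brightness = sum(vals) - bg * sum(disk),
       n_pixels = sum(disk),
       partial = partial,
       saturated = any(vals >= saturation_level))
}

#' Flag peaks that are too close together
#'
#' Every peak with any neighbor strictly closer than `min_separation` pixels
#' is flagged for exclusion; the exclusion is mutual. Peaks exactly at the
#' separation distance are kept.
#'
#' @param peaks data.frame with columns row, col
#' @param min_separation pixels
#' @return logical vector, TRUE where excluded
#' @export
filter_proximity <- function(peaks, min_separation = 21) {
  n <- nrow(peaks)
  if (n <= 1) return(rep(FALSE, n))
  d <- as.matrix(stats::dist(peaks[, c("row", "col")]))
  diag(d) <- Inf
  unname(apply(d < min_separation, 1, any))
}

#' Estimate the constant ghost offset from pairwise displacements
#'
#' Back reflections produce a faint duplicate of every bright peak at a
#' constant pixel displacement. The offset is estimated as the modal
#' displacement vector (1 px binning) over all bright-to-faint peak pairs
#' across many frames.
#'
#' @param peak_tables list of per-frame peak data.frames (row, col,
#'   brightness)
#' @param max_offset consider displacements with both components within
#'   this magnitude, pixels
#' @param min_pairs minimum number of candidate pairs required
#' @return `(drow, dcol)` estimated offset
#' @export
estimate_ghost_offset <- function(peak_tables, max_offset = 50,
                                  min_pairs = 20) {
  dr <- numeric(0); dc <- numeric(0)
  for (pk in peak_tables) {
    n <- nrow(pk)
    if (n < 2) next
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      if (pk$brightness[j] >= pk$brightness[i]) next  # ghost is fainter
      ddr <- pk$row[j] - pk$row[i]; ddc <- pk$col[j] - pk$col[i]
      if (abs(ddr) <= max_offset && abs(ddc) <= max_offset) {
        dr <- c(dr, ddr); dc <- c(dc, ddc)
      }
    }
  }
  if (length(dr) < min_pairs)
    stop("too few peak pairs to estimate the ghost offset (", length(dr),
         " < ", min_pairs, ")")
  key <- paste(round(dr), round(dc))
  mode_key <- names(sort(table(key), decreasing = TRUE))[1]
  sel <- key == mode_key
  c(drow = mean(dr[sel]), dcol = mean(dc[sel]))
}

#' Flag back-reflection ghost peaks
#'
#' For each ordered peak pair whose displacement matches the constant ghost
#' offset within the tolerance, the fainter member is flagged as a ghost.
#' For equal brightness the member displaced along the offset direction is
#' flagged (the documented tie-break).
#'
#' @param peaks data.frame with columns row, col, brightness
#' @param offset `(drow, dcol)` ghost displacement, pixels
#' @param tolerance match tolerance (Euclidean), pixels
#' @return logical vector, TRUE where flagged as ghost
#' @export
filter_ghosts <- function(peaks, offset, tolerance = 2) {
  n <- nrow(peaks)
  ghost <- rep(FALSE, n)
  if (n < 1) stop("no peaks")
  if (n == 1) return(ghost)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ddr <- peaks$row[j] - peaks$row[i]
    ddc <- peaks$col[j] - peaks$col[i]
    if (sqrt((ddr - offset[1])^2 + (ddc - offset[2])^2) <= tolerance) {
      if (peaks$brightness[j] < peaks$brightness[i]) {
        ghost[j] <- TRUE
      } else if (peaks$brightness[j] == peaks$brightness[i]) {
        ghost[j] <- TRUE  # j is displaced along the offset direction
      }
    }
  }
  ghost
}

#' Detect and measure particle spots in one frame
#'
#' Full detection stage: DoG filter, thresholding, connected-component
#' clustering, center-of-mass localization on the DoG values, raw-image
#' brightness integration, ghost flagging and mutual proximity exclusion
#' (applied to non-ghost peaks).
#'
#' @param frame an [aero_frame()]
#' @param config a [detection_config()]
#' @return data.frame of peak records: frame_id, row, col (0-based pixels),
#'   x, y (object um), brightness, n_pixels, partial, saturated, ghost,
#'   proximity_excluded
#' @export
detect_peaks <- function(frame, config) {
  frame <- validate_frame(frame)
  dog <- dog_filter(frame$pixels, config$sigma_small, config$sigma_large)
  comp <- find_peaks(dog, config$threshold, config$connectivity)
  if (nrow(comp) == 0) {
    return(data.frame(frame_id = character(0), row = numeric(0),
                      col = numeric(0), x = numeric(0), y = numeric(0),
                      brightness = numeric(0), n_pixels = integer(0),
                      partial = logical(0), saturated = logical(0),
                      ghost = logical(0), proximity_excluded = logical(0)))
  }
  labs <- sort(unique(comp$label))
  recs <- lapply(labs, function(l) {
    cl <- comp[comp$label == l, ]
    # center of mass over the measured (raw) values of the selected pixels;
    # the DoG image only selects the cluster. DoG weights would inherit a
    # localization bias from the negative annulus of nearby bright spots.
    cl$value <- frame$pixels[cbind(cl$row + 1L, cl$col + 1L)]
    cen <- peak_centroid(cl)
    br <- integrate_brightness(frame$pixels, cen,
                               radius = config$integration_radius,
                               saturation_level = frame$camera$saturation_level,
                               annulus_subtract = isTRUE(config$annulus_subtract))
    data.frame(row = cen[1], col = cen[2], brightness = br$brightness,
               n_pixels = nrow(cl), partial = br$partial,
               saturated = br$saturated)
  })
  pk <- do.call(rbind, recs)
  pk$ghost <- FALSE
  if (!is.null(config$ghost_offset) && !identical(config$ghost_offset, "auto"))
    pk$ghost <- filter_ghosts(pk, config$ghost_offset, config$ghost_tolerance)
  pk$proximity_excluded <- FALSE
  keep <- !pk$ghost
  if (sum(keep) > 1)
    pk$proximity_excluded[keep] <-
      filter_proximity(pk[keep, ], config$min_separation)
  obj <- pixels_to_object_coords(as.matrix(pk[, c("row", "col")]),
                                 frame$camera)
  pk <- cbind(frame_id = frame$frame_id, pk, x = obj[, 1], y = obj[, 2])
  rownames(pk) <- NULL
  pk[, c("frame_id", "row", "col", "x", "y", "brightness", "n_pixels",
         "partial", "saturated", "ghost", "proximity_excluded")]
}
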