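#' Maximum measurable speed of the double-flash scheme
#'
#' A particle must stay inside the illuminated spot for both flashes, so the
#' lateral spot extent divided by the inter-pulse delay caps the measurable
#' speed: 0.5 mm FWHM over 0.5 us gives 1000 m/s.
#'
#' @param spot_fwhm_mm laser-spot FWHM, mm
#' @param delay_us inter-pulse delay, us
#' @return ceiling speed, m/s
#' @export
velocity_ceiling <- function(spot_fwhm_mm, delay_us) {
  stopifnot(spot_fwhm_mm > 0, delay_us > 0)
  mm_to_m(spot_fwhm_mm) / us_to_s(delay_us)
}

#' Minimum speed to clear a focus between consecutive pulses
#'
#' The particle must traverse the focus diameter within one inter-pulse
#' period so that no particle is exposed twice: `fwhm * repetition rate`.
#' At 4.4 MHz and a 1 um focus this is 4.4 m/s.
#'
#' @param focus_fwhm_um focus diameter (FWHM), um
#' @param rep_rate_hz X-ray pulse repetition rate, Hz
#' @return minimum clearing speed, m/s
#' @export
focus_clearing_speed <- function(focus_fwhm_um, rep_rate_hz) {
  stopifnot(focus_fwhm_um > 0, rep_rate_hz > 0)
  um_to_m(focus_fwhm_um) * rep_rate_hz
}

#' Pair the two flash images of each particle
#'
#' Each double exposure contains two images per moving particle. Candidate
#' pairs are peak pairs whose object-plane displacement has a positive
#' component along the flow direction and magnitude at most
#' `max_speed * pulse_delay`; matching is mutual nearest neighbor among
#' candidates (ties broken by smallest deviation from the frame's median
#' candidate displacement). Ghost- and proximity-excluded peaks must be
#' removed beforehand ([detect_peaks()] flags them). Which image is the
#' first flash is not recoverable from a single exposure, so speeds are
#' magnitudes with direction taken from the flow prior.
#'
#' @param peaks data.frame of peaks of one frame with columns x, y (object
#'   um) and optionally brightness
#' @param pulse_delay us (> 0)
#' @param max_speed gating speed, m/s (default from [velocity_ceiling()]
#'   with the standard 0.5 mm spot)
#' @param flow_direction unit vector `(x, y)` of the flow in object
#'   coordinates; default `(0, 1)`, downwards
#' @param brightness_gate optional max relative brightness difference of a
#'   pair (e.g. 0.5); NULL disables the gate
#' @return data.frame of track records: one row per peak with columns of the
#'   input plus `paired`, `partner` (row index of the partner peak or NA),
#'   `dx`, `dy` (object um, flash1 -> flash2), `displacement` (um),
#'   `velocity` (m/s, NA when unpaired). Each physical particle yields one
#'   paired row (the upstream member carries the pair) and its partner row
#'   is marked `is_second = TRUE`.
#' @export
pair_flashes <- function(peaks, pulse_delay, max_speed = 1000,
                         flow_direction = c(0, 1), brightness_gate = NULL) {
  if (is.null(pulse_delay) || is.na(pulse_delay) || pulse_delay <= 0)
    stop("pulse_delay must be positive")
  n <- nrow(peaks)
  fd <- flow_direction / sqrt(sum(flow_direction^2))
  max_disp <- max_speed * pulse_delay  # m/s * us = um
  out <- peaks
  out$paired <- rep(FALSE, n)
  out$partner <- rep(NA_integer_, n)
  out$is_second <- rep(FALSE, n)
  out$dx <- rep(NA_real_, n); out$dy <- rep(NA_real_, n)
  out$displacement <- rep(NA_real_, n)
  out$velocity <- rep(NA_real_, n)
  if (n < 2) return(out)
  dx <- outer(peaks$x, peaks$x, function(a, b) b - a)
  dy <- outer(peaks$y, peaks$y, function(a, b) b - a)
  along <- dx * fd[1] + dy * fd[2]
  dist <- sqrt(dx^2 + dy^2)
  ok <- along > 0 & dist <= max_disp
  diag(ok) <- FALSE
  if (!is.null(brightness_gate) && "brightness" %in% names(peaks)) {
    bi <- peaks$brightness
    rel <- abs(outer(bi, bi, `-`)) / outer(bi, bi, pmax)
    ok <- ok & rel <= brightness_gate
  }
  if (!any(ok)) return(out)
  # nearest neighbor on displacement magnitude; near-ties resolved towards
  # the frame's median candidate displacement
  med_disp <- stats::median(dist[ok])
  score <- dist + 1e-6 * abs(dist - med_disp)
  score[!ok] <- Inf
  # mutual nearest neighbor on the tie-broken score
  nn_fwd <- apply(score, 1, which.min)     # best downstream partner of i
  nn_bwd <- apply(score, 2, which.min)     # best upstream partner of j
  for (i in seq_len(n)) {
    j <- nn_fwd[i]
    if (is.finite(score[i, j]) && nn_bwd[j] == i && !out$paired[i] &&
        !out$paired[j]) {
      out$paired[c(i, j)] <- TRUE
      out$partner[i] <- j; out$partner[j] <- i
      out$is_second[j] <- TRUE
      out$dx[i] <- dx[i, j]; out$dy[i] <- dy[i, j]
      out$displacement[i] <- dist[i, j]
      out$velocity[i] <- dist[i, j] / pulse_delay  # um/us = m/s
      out$dx[j] <- -dx[i, j]; out$dy[j] <- -dy[i, j]
      out$displacement[j] <- dist[i, j]
      out$velocity[j] <- out$velocity[i]
    }
  }
  out
}

#' Per-group speed statistics
#'
#' Descriptive statistics of track speeds grouped by acquisition condition
#' (injector distance and/or entrance pressure); feeds the jet-dynamics
#' fits.
#'
#' @param tracks data.frame with a `velocity` column (NA for unpaired) and
#'   the grouping columns
#' @param by character vector of grouping column names
#' @return data.frame with one row per group: group keys, `mean_speed`,
#'   `sd_speed`, `n`
#' @export
speed_statistics <- function(tracks, by = c("injector_distance")) {
  v <- tracks$velocity
  keep <- !is.na(v) & !duplicated_pairs(tracks)
  t2 <- tracks[keep, , drop = FALSE]
  if (nrow(t2) == 0) {
    warning("no paired tracks")
    return(data.frame())
  }
  key <- interaction(t2[, by, drop = FALSE], drop = TRUE)
  agg <- do.call(rbind, lapply(split(t2, key), function(g) {
    cbind(g[1, by, drop = FALSE],
          data.frame(mean_speed = mean(g$velocity),
                     sd_speed = stats::sd(g$velocity),
                     n = nrow(g)))
  }))
  rownames(agg) <- NULL
  agg
}

# TRUE for the second member of each pair, so each physical particle is
# counted once in statistics.
duplicated_pairs <- function(tracks) {
  if (!"is_second" %in% names(tracks)) return(rep(FALSE, nrow(tracks)))
  tracks$is_second
}
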