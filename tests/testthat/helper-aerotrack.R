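# Shared fixtures and independent oracles for the test suite.

# Small, quiet camera for photometric tests (no background, no dark noise).
quiet_camera <- function(n = 256, scale = 1.14) {
  camera_model(n_pixels_x = n, n_pixels_y = n,
               dark_noise_sigma = 0, background_rate = 0,
               pixel_scale_object = scale)
}

# Realistic small camera (background + dark noise as in the instrument).
noisy_camera <- function(n = 256, scale = 1.14) {
  camera_model(n_pixels_x = n, n_pixels_y = n, pixel_scale_object = scale)
}

# Independent discrete convolution oracle: blur an image with a truncated,
# normalized, sampled Gaussian kernel by direct summation.
oracle_gaussian_blur <- function(img, sigma, radius = 2 * ceiling(3 * sigma)) {
  off <- -radius:radius
  k1 <- exp(-off^2 / (2 * sigma^2))
  k2 <- outer(k1, k1)
  k2 <- k2 / sum(k2)
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (a in off) for (b in off) {
      ii <- min(max(i + a, 1), nr)   # replicate boundary
      jj <- min(max(j + b, 1), nc)
      acc <- acc + img[ii, jj] * k2[a + radius + 1, b + radius + 1]
    }
    out[i, j] <- acc
  }
  out
}

# Exhaustive connected-component labeling oracle: repeated neighbor
# expansion on the full boolean mask.
oracle_label <- function(mask, connectivity = 4) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  offs <- if (connectivity == 4) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
          else {
            o <- expand.grid(-1:1, -1:1)
            o <- o[!(o[, 1] == 0 & o[, 2] == 0), ]
            split(as.matrix(o), seq_len(nrow(o)))
          }
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || lab[i, j] > 0) next
    cur <- cur + 1L
    queue <- list(c(i, j))
    lab[i, j] <- cur
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (o in offs) {
        q <- p + o
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            mask[q[1], q[2]] && lab[q[1], q[2]] == 0) {
          lab[q[1], q[2]] <- cur
          queue <- c(queue, list(q))
        }
      }
    }
  }
  lab
}

# Zero-truncated Poisson probability mass (closed form).
ztpois_pmf <- function(k, lambda) {
  stats::dpois(k, lambda) / (1 - exp(-lambda))
}

# Epstein free-molecular drag (diffuse reflection with full thermal
# accommodation): C_D = (16 / (3 sqrt(pi) S)) (1 + pi/8), S = v / c_m.
oracle_epstein_drag <- function(v_rel, state, d_p, gas) {
  Rs <- 8.31446261815324 / gas$molar_mass
  c_m <- sqrt(2 * Rs * state$T)
  S <- abs(v_rel) / c_m
  Cd <- 16 / (3 * sqrt(pi) * S) * (1 + pi / 8)
  sign(v_rel) * 0.5 * state$rho * Cd * pi * (d_p / 2)^2 * v_rel^2
}
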