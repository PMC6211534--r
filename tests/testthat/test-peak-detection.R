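test_that("DoG filter preserves linearity and kills constants", {
  img <- matrix(rnorm(64 * 64), 64, 64)
  const <- matrix(3.7, 64, 64)
  expect_true(all(abs(dog_filter(const, 3, 6)) < 1e-8))
  expect_equal(dog_filter(2 * img, 3, 6), 2 * dog_filter(img, 3, 6),
               tolerance = 1e-10)
  expect_error(dog_filter(1:10, 3, 6), "matrix")
  expect_error(dog_filter(img, 6, 3))
})

test_that("DoG impulse response matches a direct discrete convolution oracle", {
  img <- matrix(0, 41, 41)
  img[21, 21] <- 1
  got <- dog_filter(img, 3, 6)
  ora <- oracle_gaussian_blur(img, 3) - oracle_gaussian_blur(img, 6)
  expect_equal(got[21, 21], ora[21, 21], tolerance = 0.01)
  # analytic center value of the continuous DoG
  expect_equal(got[21, 21], 1 / (2 * pi * 9) - 1 / (2 * pi * 36),
               tolerance = 0.01)
})

test_that("supra-threshold clusters are labeled like the exhaustive oracle", {
  img <- matrix(0, 16, 16)
  expect_equal(nrow(find_peaks(img + 0.1, 0.5)), 0)

  blob <- matrix(0, 16, 16)
  blob[5, 5:8] <- 1; blob[6, 6] <- 1
  expect_equal(length(unique(find_peaks(blob, 0.5)$label)), 1)

  two <- matrix(0, 16, 16)
  two[3, 3] <- 1; two[3, 4] <- 1
  two[12, 12] <- 1
  expect_equal(length(unique(find_peaks(two, 0.5)$label)), 2)

  # property: random masks agree with repeated-expansion labeling, 4 and 8
  set.seed(21)
  for (rep in 1:10) {
    m <- matrix(runif(16 * 16) < 0.3, 16, 16)
    img <- matrix(0, 16, 16); img[m] <- 1
    for (conn in c(4, 8)) {
      pk <- find_peaks(img, 0.5, connectivity = conn)
      ora <- oracle_label(m, conn)
      expect_equal(length(unique(pk$label)), max(ora))
      # same pixels grouped together
      got_grp <- split(paste(pk$row, pk$col),
                       pk$label)
      ora_idx <- which(m, arr.ind = TRUE)
      ora_grp <- split(paste(ora_idx[, 1] - 1, ora_idx[, 2] - 1),
                       ora[m])
      norm <- function(g) sort(vapply(g, function(s)
        paste(sort(s), collapse = ";"), ""))
      expect_equal(unname(norm(got_grp)), unname(norm(ora_grp)))
    }
  }
})

test_that("centroid is the intensity-weighted center of mass", {
  sym <- data.frame(row = c(4, 5, 6, 5, 5), col = c(5, 5, 5, 4, 6),
                    value = c(1, 2, 1, 1, 1))
  expect_equal(peak_centroid(sym), c(row = 5, col = 5))
  two <- data.frame(row = c(0, 0), col = c(0, 2), value = c(1, 3))
  expect_equal(peak_centroid(two), c(row = 0, col = 1.5))
  one <- data.frame(row = 7, col = 9, value = 0.4)
  expect_equal(peak_centroid(one), c(row = 7, col = 9))
  expect_error(peak_centroid(one[0, ]), "empty")
  expect_error(peak_centroid(data.frame(row = 1, col = 1, value = 0)),
               "weight")
})

test_that("brightness integrates raw pixels within the 10 px disk", {
  img <- matrix(0, 64, 64)
  expect_equal(integrate_brightness(img, c(31, 31))$brightness, 0)

  # brute-force lattice-point count oracle for r <= 10
  n_disk <- sum(outer((-15:15)^2, (-15:15)^2, `+`) <= 100)
  b <- 2.5
  r <- integrate_brightness(matrix(b, 64, 64), c(31, 31))
  expect_equal(r$brightness, n_disk * b)
  expect_equal(r$n_pixels, n_disk)
  expect_equal(n_disk, 317)  # frozen oracle value

  # a rendered 157-photon spot well inside the disk integrates to ~157
  cam <- quiet_camera(64)
  sc <- scene_spec(particle(40, c(0, 0)), pulse_pair = 50, psf_sigma = 2)
  fr <- render_frame(sc, cam, shot_noise = FALSE, dark_noise = FALSE)$frame
  got <- integrate_brightness(fr$pixels, c(31.5, 31.5))$brightness
  expect_equal(got, 157, tolerance = 0.005)

  edge <- integrate_brightness(matrix(1, 64, 64), c(3, 31))
  expect_true(edge$partial)
  expect_error(integrate_brightness(img, c(-5, 31)), "outside")
})

test_that("proximity exclusion applies the strict 21 px rule mutually", {
  pk <- data.frame(row = c(0, 20.5), col = c(0, 0))
  expect_equal(filter_proximity(pk), c(TRUE, TRUE))
  pk21 <- data.frame(row = c(0, 21), col = c(0, 0))
  expect_equal(filter_proximity(pk21), c(FALSE, FALSE))
  expect_equal(filter_proximity(data.frame(row = 5, col = 5)), FALSE)
  # permutation invariance
  pk3 <- data.frame(row = c(0, 15, 80), col = c(0, 0, 0))
  expect_equal(filter_proximity(pk3)[c(2, 3, 1)],
               filter_proximity(pk3[c(2, 3, 1), ]))
})

test_that("ghost peaks at the constant offset are flagged, fainter member loses", {
  pk <- data.frame(row = c(10, 25), col = c(10, 13),
                   brightness = c(1000, 100))
  expect_equal(filter_ghosts(pk, offset = c(15, 3)), c(FALSE, TRUE))
  tie <- data.frame(row = c(10, 25), col = c(10, 13),
                    brightness = c(500, 500))
  expect_equal(filter_ghosts(tie, offset = c(15, 3)), c(FALSE, TRUE))
  expect_error(filter_ghosts(pk[0, ], offset = c(15, 3)), "no peaks")
})

test_that("auto ghost-offset estimation recovers the rendered offset within 1 px", {
  cam <- noisy_camera(256)
  cfg <- detection_config(threshold = 3)
  tabs <- list()
  set.seed(31)
  for (i in 1:15) {
    pts <- do.call(rbind, lapply(1:3, function(j)
      particle(120, c(runif(1, -80, 80), runif(1, -100, 60)))))
    sc <- scene_spec(pts, pulse_pair = 50,
                     ghost_offset = c(15, 3), ghost_intensity_fraction = 0.1)
    fr <- render_frame(sc, cam)$frame
    tabs[[i]] <- detect_peaks(fr, cfg)
  }
  est <- estimate_ghost_offset(tabs)
  expect_lt(abs(est[1] - 15), 1)
  expect_lt(abs(est[2] - 3), 1)
  expect_error(estimate_ghost_offset(tabs[1]), "too few")
})

test_that("detection recall and false-discovery rate on bright synthetic frames", {
  cam <- noisy_camera(256)
  cfg <- detection_config(threshold = 3)
  n_true <- 0; n_found <- 0; n_det <- 0; n_matched_det <- 0
  set.seed(77)
  for (i in 1:100) {
    # 4 well-separated particles on a jittered grid, single flash
    centers <- expand.grid(x = c(-60, 60), y = c(-60, 60))
    pts <- do.call(rbind, lapply(seq_len(4), function(j)
      particle(100, c(centers$x[j] + runif(1, -10, 10),
                      centers$y[j] + runif(1, -10, 10)))))
    sc <- scene_spec(pts, pulse_pair = 50)
    r <- render_frame(sc, cam)
    pk <- detect_peaks(r$frame, cfg)
    pk <- pk[!pk$ghost, ]
    n_true <- n_true + nrow(r$truth)
    n_det <- n_det + nrow(pk)
    if (nrow(pk) > 0) {
      d <- outer(r$truth$row, pk$row, `-`)^2 +
           outer(r$truth$col, pk$col, `-`)^2
      n_found <- n_found + sum(apply(d, 1, min) < 9)
      n_matched_det <- n_matched_det + sum(apply(d, 2, min) < 9)
    }
  }
  expect_gte(n_found / n_true, 0.95)
  expect_lte(1 - n_matched_det / n_det, 0.05)
})

test_that("noiseless localization bias is below 0.2 px and brightness is sub-pixel invariant", {
  cam <- quiet_camera(128)
  cfg <- detection_config(threshold = 0.5)
  set.seed(13)
  errs <- c(); brs <- c()
  for (i in 1:20) {
    xy <- runif(2, -5, 5) * cam$pixel_scale_object
    sc <- scene_spec(particle(100, xy), pulse_pair = 50)
    r <- render_frame(sc, cam, shot_noise = FALSE, dark_noise = FALSE)
    pk <- detect_peaks(r$frame, cfg)
    expect_equal(nrow(pk), 1)
    errs <- c(errs, sqrt((pk$row - r$truth$row)^2 +
                           (pk$col - r$truth$col)^2))
    brs <- c(brs, pk$brightness)
  }
  expect_lt(max(errs), 0.2)
  expect_lt(diff(range(brs)) / mean(brs), 0.01)
})
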