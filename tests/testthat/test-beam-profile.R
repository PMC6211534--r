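test_that("transverse Gaussian fit recovers FWHM = 2.355 sigma", {
  set.seed(3)
  x <- rnorm(1e5, 0, 12)
  pr <- transverse_profile(x)
  expect_equal(pr$fwhm, sigma_to_fwhm(12), tolerance = 0.01)
  expect_equal(pr$center, 0, tolerance = 0.2)
  # translation equivariance
  pr2 <- transverse_profile(x + 40)
  expect_equal(pr2$center - pr$center, 40, tolerance = 1e-9)
  expect_equal(pr2$fwhm, pr$fwhm, tolerance = 1e-12)
  # degenerate and undersized inputs
  expect_error(transverse_profile(rep(5, 100)), "degenerate")
  expect_error(transverse_profile(rnorm(10)), "at least")
})

test_that("Gaussian-beam envelope fit recovers exact parameters", {
  w0 <- 30; z0 <- 3.2; zR <- 1.5
  z <- seq(0.5, 8, by = 0.5)
  w <- w0 * sqrt(1 + ((z - z0) / zR)^2)
  bm <- fit_gaussian_beam(z, w)
  expect_equal(bm$waist_fwhm, w0, tolerance = 1e-8)
  expect_equal(bm$focus_distance, z0, tolerance = 1e-8)
  expect_equal(bm$divergence, w0 / (2 * zR), tolerance = 1e-8)
  # zero-residual fit on exact model data
  expect_lt(max(abs(bm$widths$residual)), 1e-6)
  # the fitted envelope evaluated at the focus equals the waist
  w_at_focus <- bm$waist_fwhm *
    sqrt(1 + ((bm$focus_distance - bm$focus_distance) /
                bm$rayleigh_range)^2)
  expect_equal(w_at_focus, bm$waist_fwhm)
})

test_that("Gaussian-beam fit under 5% width noise recovers waist and focus within 10%", {
  set.seed(8)
  w0 <- 30; z0 <- 3.2; zR <- 1.5
  z <- seq(0.5, 8, by = 1)
  w <- w0 * sqrt(1 + ((z - z0) / zR)^2) * (1 + rnorm(length(z), 0, 0.05))
  bm <- fit_gaussian_beam(z, w)
  expect_lt(abs(bm$waist_fwhm - w0) / w0, 0.1)
  expect_lt(abs(bm$focus_distance - z0) / z0, 0.1)
})

test_that("power-law pressure scalings are recovered exactly on exact data", {
  p <- c(0.5, 0.8, 1.2, 1.8)
  # exact power-law data: lm warns about the zero-residual fit
  f1 <- suppressWarnings(fit_scaling_law(p, 7 * p^-1))
  expect_equal(f1$exponent, -1, tolerance = 1e-10)
  f2 <- suppressWarnings(fit_scaling_law(p, 2 * p^-0.5))
  expect_equal(f2$exponent, -0.5, tolerance = 1e-10)
  f3 <- suppressWarnings(fit_scaling_law(p, rep(4, 4)))
  expect_equal(f3$exponent, 0, tolerance = 1e-10)
  expect_error(fit_scaling_law(p, c(-1, 1, 1, 1)), "positive")
  expect_error(fit_scaling_law(p[1:2], c(1, 2)))
})

test_that("areal density is mean count per area and Gaussian peak density is recovered", {
  d <- areal_density(10, area = 1000)
  expect_equal(d$mean_density, 1e-2)
  expect_equal(areal_density(0, 1000)$mean_density, 0)
  expect_error(areal_density(3, 0), "positive")

  # synthetic beam with known peak column density
  set.seed(15)
  sigma <- 30; L <- 200
  peak_true <- 5e-3                      # particles/um^2 at the axis
  n_mean <- peak_true * sqrt(2 * pi) * sigma * L
  counts <- rpois(400, n_mean)
  xs <- rnorm(sum(counts), 0, sigma)
  pr <- transverse_profile(xs)
  est <- areal_density(counts, area = 4 * sigma * L, profile = pr,
                       axial_length = L)
  expect_equal(est$peak_density, peak_true, tolerance = 0.05)
})

test_that("injection yield compares beam outflow to solution inflow", {
  # constructed so outflow equals inflow exactly
  conc <- 1e12; flow <- 1                # /ml, ul/min
  inflow <- conc / 1000 * flow / 60      # /s
  sigma <- 20; speed <- 50
  peak <- inflow / (sqrt(2 * pi) * sigma * speed * 1e6)
  expect_equal(injection_yield(peak, sigma, speed, conc, flow), 1)
  expect_equal(injection_yield(0, sigma, speed, conc, flow), 0)
  expect_warning(injection_yield(2 * peak, sigma, speed, conc, flow),
                 "unphysical")
  # unit invariance: same setup quoted in different flow units
  y1 <- injection_yield(peak / 2, sigma, speed, conc, flow)
  y2 <- injection_yield(peak / 2, sigma, speed, conc * 2, flow / 2)
  expect_equal(y1, y2)
})

test_that("a 30% yield built into a synthetic beam is measured back", {
  set.seed(33)
  conc <- 1e11; flow <- 2; speed <- 60; sigma <- 25; L <- 150
  yield_true <- 0.30
  inflow <- conc / 1000 * flow / 60
  peak_true <- yield_true * inflow / (sqrt(2 * pi) * sigma * speed * 1e6)
  n_mean <- peak_true * sqrt(2 * pi) * sigma * L
  counts <- rpois(3000, n_mean)
  xs <- rnorm(sum(counts), 0, sigma)
  pr <- transverse_profile(xs)
  est <- areal_density(counts, area = 1, profile = pr, axial_length = L)
  y <- injection_yield(est$peak_density, pr$sigma, speed, conc, flow)
  expect_equal(y, 0.30, tolerance = 0.02 / 0.30)
})

test_that("hit-ratio prediction is density times nominal focus area", {
  # the two ends of the measured density span
  expect_equal(100 * predict_hit_ratio(1.9e-2, 5), 37, tolerance = 0.01)
  expect_equal(100 * predict_hit_ratio(4e-4, 0.1), 3.1e-4, tolerance = 0.02)
  expect_equal(predict_hit_ratio(0, 5), 0)
  # linear in density, quadratic in FWHM (exact)
  expect_equal(predict_hit_ratio(2e-3, 2), 2 * predict_hit_ratio(1e-3, 2))
  expect_equal(predict_hit_ratio(1e-3, 4), 4 * predict_hit_ratio(1e-3, 2))
  # capped reporting
  expect_equal(predict_hit_ratio(1, 100), 1)
})

test_that("end-to-end pressure-scan recovery: fitted scaling exponents within 2 SE", {
  set.seed(55)
  pressures <- c(0.6, 0.9, 1.2, 1.6, 2.0)
  distances <- c(0.8, 1.5, 2, 2.5, 3, 3.5, 4, 5, 7, 10)
  exps <- c(waist = -1.5, focus = -0.5, div = -1)
  scan <- generate_pressure_scan(pressures, distances,
                                 waist_fwhm_ref = 40,
                                 focus_distance_ref = 3,
                                 divergence_ref = 20,
                                 waist_exponent = exps["waist"],
                                 focus_exponent = exps["focus"],
                                 divergence_exponent = exps["div"],
                                 n_per_cell = 1500,
                                 velocity_fn = function(p, z, d) 50)
  fits <- lapply(split(scan, scan$pressure), function(g) {
    wt <- t(sapply(split(g, g$distance), function(h) {
      pr <- transverse_profile(h$x)
      c(z = h$distance[1], fwhm = pr$fwhm, se = pr$fwhm_se)
    }))
    fit_gaussian_beam(wt[, "z"], wt[, "fwhm"], weights = 1 / wt[, "se"]^2)
  })
  par_tab <- data.frame(
    p = as.numeric(names(fits)),
    waist = sapply(fits, `[[`, "waist_fwhm"),
    focus = sapply(fits, `[[`, "focus_distance"),
    div = sapply(fits, `[[`, "divergence"))
  for (q in c("waist", "focus", "div")) {
    sl <- fit_scaling_law(par_tab$p, par_tab[[q]], quantity = q)
    expect_lt(abs(sl$exponent - exps[q]), 2 * sl$exponent_se)
  }
})
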