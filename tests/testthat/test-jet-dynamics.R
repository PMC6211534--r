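he <- gas_properties()

test_that("speed of sound follows sqrt(gamma R T / M)", {
  a293 <- speed_of_sound(he, 293.15)
  expect_equal(a293, 1008, tolerance = 2 / 1008)    # He near room temperature
  expect_equal(speed_of_sound(he, 4 * 293.15), 2 * a293)
  heavy <- gas_properties(molar_mass = 4 * he$molar_mass)
  expect_equal(speed_of_sound(heavy, 293.15), a293 / 2)
})

test_that("centerline Mach correlation matches its closed form and is monotone", {
  # direct evaluation oracle: A (x/d - x0/d)^(g-1) - (g+1)/(g-1) / (2 A ...)
  t <- 3.26 * (1 - 0.075)^(2 / 3)
  oracle <- t - 4 / (2 * t)
  expect_equal(mach_centerline(1.32, 1.32), oracle, tolerance = 1e-12)
  expect_equal(oracle, 2.449, tolerance = 1e-3)

  xd <- seq(1, 20, by = 0.25)
  M <- mach_centerline(xd, 1)
  expect_true(all(diff(M) > 0))
  # doubling d_eff halves x/d and lowers M
  expect_lt(mach_centerline(5, 2), mach_centerline(5, 1))
  expect_error(mach_centerline(0.1, 1), "validity")
})

test_that("isentropic relations reproduce stagnation and sonic states", {
  st0 <- isentropic_state(0, 100, 293.15, he)
  expect_equal(st0$T, 293.15)
  expect_equal(st0$p, 100)
  expect_equal(st0$v, 0)

  st1 <- isentropic_state(1, 100, 293.15, he)
  expect_equal(st1$T / 293.15, 0.75)   # (1 + 1/3)^-1 for gamma = 5/3
  expect_equal(st1$v, st1$a)

  # ideal-gas consistency: p / (rho T) constant across states
  st <- isentropic_state(c(0, 0.5, 1, 2, 5), 100, 293.15, he)
  ratio <- st$p / (st$rho * st$T)
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-12)
})

test_that("Henderson drag is odd, vanishes at rest, and matches Epstein in the FM limit", {
  st <- list(T = 250, rho = 1e-4, a = speed_of_sound(he, 250))
  d_p <- 1e-7
  expect_equal(henderson_drag(0, st, d_p, he), 0)
  expect_equal(henderson_drag(0, list(T = 250, rho = 0, a = 900), d_p, he), 0)
  f <- henderson_drag(12, st, d_p, he)
  expect_equal(henderson_drag(-12, st, d_p, he), -f)
  expect_gt(f, 0)

  # low-speed free-molecular limit: rho small so Re/S -> 0
  stfm <- list(T = 293, rho = 1e-5, a = speed_of_sound(he, 293))
  for (v in c(0.2, 1, 5)) {
    fh <- henderson_drag(v, stfm, d_p, he)
    fe <- oracle_epstein_drag(v, stfm, d_p, he)
    expect_equal(fh / fe, 1, tolerance = 0.1)
  }
})

test_that("particle propagation: equilibrium, monotone approach, tolerance convergence", {
  flow <- jet_flow_field(1.0)
  # drag sign: the particle never overtakes the gas and approaches it
  # monotonically from below in the accelerating flow
  prof <- propagate_particle(flow, 100, v0 = 5, x_end_mm = 25)
  expect_true(all(prof$v <= prof$v_gas + 1e-9))
  expect_true(all(diff(prof$v) > -1e-9))          # monotone from below
  expect_gt(attr(prof, "terminal_velocity"), 5)

  # halving the tolerance moves the terminal velocity by < 0.1%
  v_a <- attr(propagate_particle(flow, 100, v0 = 5, x_end_mm = 25,
                                 rtol = 1e-6), "terminal_velocity")
  v_b <- attr(propagate_particle(flow, 100, v0 = 5, x_end_mm = 25,
                                 rtol = 5e-7), "terminal_velocity")
  v_c <- attr(propagate_particle(flow, 100, v0 = 5, x_end_mm = 25,
                                 rtol = 1e-10), "terminal_velocity")
  expect_lt(abs(v_a - v_b) / v_b, 1e-3)
  expect_lt(abs(v_b - v_c) / v_c, 1e-3)
  expect_error(propagate_particle(flow, 100, v0 = 0), "positive")
})

test_that("gas state is monotone along the expansion", {
  flow <- jet_flow_field(1.5)
  st <- flow$state_at(seq(1, 25, by = 0.5))
  expect_true(all(diff(st$M) > 0))
  expect_true(all(diff(st$T) < 0))
  expect_true(all(diff(st$p) < 0))
  expect_true(all(diff(st$rho) < 0))
})

test_that("Stokes number composes relaxation time and orifice flow velocity", {
  # independent algebraic oracle: St = [C_c rho_p d_p^2/(18 mu)] *
  #   [4 F_m/(rho_l pi d_f^2)] / (d_f/2); all-unity inputs -> 4/(9 pi)
  expect_equal(stokes_number(1, 1, 1, 1, 1, 1, 1), 4 / (9 * pi))
  base <- stokes_number(1, 1050, 1e-7, 2e-5, 1e-6, 1e-3, 1.5e-3)
  # doubling d_p at fixed C_c quadruples St
  expect_equal(stokes_number(1, 1050, 2e-7, 2e-5, 1e-6, 1e-3, 1.5e-3) / base, 4)
  # doubling d_f at fixed F_m divides St by 8 (u ~ d_f^-2, St ~ u/d_f)
  expect_equal(stokes_number(1, 1050, 1e-7, 2e-5, 1e-6, 1e-3, 3.0e-3) / base,
               1 / 8)
  # slip correction sanity: C_c -> 1 as Kn -> 0, grows with Kn
  expect_equal(cunningham_slip(1e-6), 1, tolerance = 1e-4)
  expect_gt(cunningham_slip(100), cunningham_slip(10))
})

test_that("velocity-collapse fit recovers parameters and honors zero-noise data", {
  set.seed(29)
  St <- exp(seq(log(0.1), log(2000), length.out = 25))
  pars <- c(A = 0.486, B = 0.002, C = 0.088)
  y <- collapse_model_default(St, pars["A"], pars["B"], pars["C"])
  fit0 <- fit_velocity_collapse(St, y)
  expect_lt(max(abs(resid(fit0$fit))), 1e-10)
  expect_equal(fit0$A, unname(pars["A"]), tolerance = 1e-6)

  yn <- y * (1 + rnorm(length(y), 0, 0.01))
  fit <- fit_velocity_collapse(St, yn)
  expect_lt(abs(fit$A - pars["A"]) / pars["A"], 0.05)
  expect_lt(abs(fit$C - pars["C"]) / pars["C"], 0.05)
  # fitted curve is monotone non-decreasing over the data range (diagnostic)
  grid <- collapse_model_default(sort(St), fit$A, fit$B, fit$C)
  expect_true(all(diff(grid) >= 0))
})

test_that("terminal velocities collapse at equal Stokes number within 2%", {
  c0 <- speed_of_sound(he, 293.15)
  pairs <- list(c(p1 = 0.8, d1 = 100, p2 = 1.6),
                c(p1 = 0.6, d1 = 220, p2 = 1.2),
                c(p1 = 1.0, d1 = 70, p2 = 1.8))
  for (pr in pairs) {
    St1 <- stokes_number_for_conditions(pr["p1"], pr["d1"])
    d2 <- uniroot(function(d) stokes_number_for_conditions(pr["p2"], d) - St1,
                  c(10, 600))$root
    v1 <- jet_terminal_velocity(pr["p1"], pr["d1"], v0 = 2)
    v2 <- jet_terminal_velocity(pr["p2"], d2, v0 = 2)
    expect_equal(v1 / c0, v2 / c0, tolerance = 0.02)
  }
})

test_that("entrance velocity and effective orifice ratio are recovered from speeds", {
  geom <- injector_geometry(1.5, 0.880)
  flow <- jet_flow_field(1.2, geometry = geom)
  prof <- propagate_particle(flow, 220, v0 = 10, x_end_mm = 20)
  xs <- c(2, 5, 10, 20)
  dat <- data.frame(pressure = 1.2, diameter = 220, x = xs,
                    v = approx(prof$x_mm, prof$v, xout = xs)$y)
  fit <- fit_entrance_parameters(dat, ratio_start = 0.8, v0_start = 5,
                                 maxit = 400)
  expect_lt(abs(fit$effective_diameter_ratio - 0.880) / 0.880, 0.02)
  expect_lt(fit$sse, 1e-2)
  expect_error(fit_entrance_parameters(dat[1, ]), "at least 2")
})
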