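#' Carrier-gas properties
#'
#' Defaults describe helium: monatomic (heat-capacity ratio 5/3), dynamic
#' viscosity 1.96e-5 Pa s at 293 K with a power-law temperature scaling
#' (exponent 0.7).
#'
#' @param species label
#' @param gamma heat-capacity ratio (> 1)
#' @param molar_mass kg/mol
#' @param viscosity dynamic viscosity at `reference_T`, Pa s
#' @param reference_T reference temperature for the viscosity, K
#' @param viscosity_exponent power-law exponent of viscosity vs temperature
#' @return object of class `gas_properties`
#' @export
gas_properties <- function(species = "He", gamma = 5 / 3,
                           molar_mass = 4.0026e-3,
                           viscosity = 1.96e-5, reference_T = 293,
                           viscosity_exponent = 0.7) {
  stopifnot(gamma > 1, molar_mass > 0, viscosity > 0, reference_T > 0)
  structure(list(species = species, gamma = gamma, molar_mass = molar_mass,
                 viscosity = viscosity, reference_T = reference_T,
                 viscosity_exponent = viscosity_exponent),
            class = "gas_properties")
}

#' @rdname gas_properties
#' @param gas a `gas_properties`
#' @param T_k temperature, K
#' @export
gas_viscosity <- function(gas, T_k) {
  gas$viscosity * (T_k / gas$reference_T)^gas$viscosity_exponent
}

#' Speed of sound of an ideal gas
#'
#' `a = sqrt(gamma R T / molar mass)`; about 1008 m/s for helium near room
#' temperature.
#'
#' @param gas a [gas_properties()]
#' @param T_k temperature, K
#' @return m/s
#' @export
speed_of_sound <- function(gas, T_k) {
  stopifnot(all(T_k > 0))
  sqrt(gas$gamma * .R_GAS * T_k / gas$molar_mass)
}

#' Injector exit-orifice geometry
#'
#' The physical exit orifice of the aerodynamic lens and the ratio of
#' effective to physical diameter. The effective diameter accounts for the
#' boundary layer at the orifice; 0.880 is the value recovered for this
#' injector at its low nozzle Reynolds numbers (thin-plate orifices at
#' Re > 500 show about 0.943).
#'
#' @param orifice_diameter physical diameter, mm
#' @param effective_diameter_ratio effective/physical diameter, in (0, 1]
#' @return object of class `injector_geometry`
#' @export
injector_geometry <- function(orifice_diameter = 1.5,
                              effective_diameter_ratio = 0.880) {
  stopifnot(orifice_diameter > 0, effective_diameter_ratio > 0,
            effective_diameter_ratio <= 1)
  structure(list(orifice_diameter = orifice_diameter,
                 effective_diameter_ratio = effective_diameter_ratio),
            class = "injector_geometry")
}

#' Centerline Mach number of a free-jet expansion
#'
#' Far-field power-law correlation for the Mach number along the centerline
#' of an underexpanded free jet from a round orifice,
#' `M = A ((x - x0)/d)^(gamma-1) - ((gamma+1)/(gamma-1)) /
#' (2 A ((x - x0)/d)^(gamma-1))`, with the published monatomic-gas
#' constants A = 3.26, x0/d = 0.075. Valid downstream of the near-orifice
#' region (x/d above `validity_bound`); strictly increasing in x there.
#'
#' @param x_mm axial distance from the orifice, mm (vectorized)
#' @param d_eff_mm effective orifice diameter, mm
#' @param gamma heat-capacity ratio (constants are for monatomic 5/3)
#' @param A_const,x0_over_d correlation constants
#' @param validity_bound smallest usable x/d
#' @return Mach number
#' @export
mach_centerline <- function(x_mm, d_eff_mm, gamma = 5 / 3,
                            A_const = 3.26, x0_over_d = 0.075,
                            validity_bound = 0.5) {
  xd <- x_mm / d_eff_mm
  if (any(xd < validity_bound))
    stop("x/d below the far-field validity bound (", validity_bound,
         "); the correlation does not describe the near-orifice region")
  t <- A_const * (xd - x0_over_d)^(gamma - 1)
  t - (gamma + 1) / (gamma - 1) / (2 * t)
}

#' Isentropic gas state from the Mach number
#'
#' Local temperature, pressure, density and velocity of the expanding gas
#' given the stagnation (reservoir) state:
#' `T = T0 (1 + (gamma-1)/2 M^2)^-1`, `p = p0 (T/T0)^(gamma/(gamma-1))`,
#' `rho = rho0 (T/T0)^(1/(gamma-1))`, `v = M a(T)`.
#'
#' @param M Mach number (vectorized, >= 0)
#' @param p0 stagnation pressure, Pa
#' @param T0 stagnation temperature, K
#' @param gas a [gas_properties()]
#' @return data.frame with columns M, T, p, rho, a, v
#' @export
isentropic_state <- function(M, p0, T0, gas = gas_properties()) {
  stopifnot(all(M >= 0), p0 > 0, T0 > 0)
  g <- gas$gamma
  Tr <- 1 / (1 + (g - 1) / 2 * M^2)
  T_loc <- T0 * Tr
  p <- p0 * Tr^(g / (g - 1))
  rho0 <- p0 * gas$molar_mass / (.R_GAS * T0)
  rho <- rho0 * Tr^(1 / (g - 1))
  a <- speed_of_sound(gas, T_loc)
  data.frame(M = M, T = T_loc, p = p, rho = rho, a = a, v = M * a)
}

#' Choked-orifice flow state and mass flow rate
#'
#' Isentropic estimate of the flow through the lens exit orifice: the flow
#' chokes (M = 1) at the effective throat area, with the entrance pressure
#' and room temperature as the stagnation state. Returns the sonic gas
#' state at the orifice, the mass flow rate and the average flow velocity
#' through the physical orifice, `u = 4 F_m / (rho pi d_f^2)`.
#'
#' @param entrance_pressure mbar (stagnation)
#' @param gas a [gas_properties()]
#' @param geometry an [injector_geometry()]
#' @param T0 stagnation temperature, K
#' @return list: `state` (sonic state at the throat), `F_m` (kg/s),
#'   `u` (m/s), `rho_l` (kg/m^3, gas density at the orifice)
#' @export
orifice_flow <- function(entrance_pressure, gas = gas_properties(),
                         geometry = injector_geometry(), T0 = 293.15) {
  p0 <- mbar_to_pa(entrance_pressure)
  st <- isentropic_state(1, p0, T0, gas)
  d_eff <- mm_to_m(geometry$orifice_diameter *
                     geometry$effective_diameter_ratio)
  d_f <- mm_to_m(geometry$orifice_diameter)
  A_eff <- pi * (d_eff / 2)^2
  F_m <- st$rho * st$v * A_eff
  u <- 4 * F_m / (st$rho * pi * d_f^2)
  list(state = st, F_m = F_m, u = u, rho_l = st$rho)
}

#' One-dimensional free-jet flow field
#'
#' Combines the centerline Mach correlation with the isentropic relations
#' into a flow field evaluable at any axial distance, with the entrance
#' pressure as the stagnation pressure and room temperature as the
#' stagnation temperature.
#'
#' @param entrance_pressure mbar
#' @param gas a [gas_properties()]
#' @param geometry an [injector_geometry()]
#' @param T0 stagnation temperature, K
#' @return object of class `jet_flow_field` with `$state_at(x_mm)`
#'   returning the [isentropic_state()] row(s) at `x_mm`, plus the
#'   orifice-flow quantities of [orifice_flow()]
#' @export
jet_flow_field <- function(entrance_pressure, gas = gas_properties(),
                           geometry = injector_geometry(), T0 = 293.15) {
  p0 <- mbar_to_pa(entrance_pressure)
  d_eff_mm <- geometry$orifice_diameter * geometry$effective_diameter_ratio
  of <- orifice_flow(entrance_pressure, gas, geometry, T0)
  state_at <- function(x_mm) {
    M <- mach_centerline(x_mm, d_eff_mm, gas$gamma)
    isentropic_state(M, p0, T0, gas)
  }
  structure(list(entrance_pressure = entrance_pressure, gas = gas,
                 geometry = geometry, T0 = T0, d_eff_mm = d_eff_mm,
                 x_min_mm = 0.5 * d_eff_mm,
                 F_m = of$F_m, u = of$u, rho_l = of$rho_l,
                 state_at = state_at),
            class = "jet_flow_field")
}

#' Henderson sphere-drag force
#'
#' Semi-empirical drag correlation for spheres across the continuum,
#' transition and free-molecular regimes, evaluated with the particle
#' Reynolds and Mach numbers of the relative flow and the wall-to-gas
#' temperature ratio. Accurate under the free-molecular conditions of
#' sub-micron particles in the expanding jet (particle Knudsen numbers of
#' order 1e2-1e3). The force opposes the relative velocity and is odd in
#' it; zero gas density or zero relative speed gives zero force.
#'
#' @param v_rel relative velocity `gas - particle`, m/s (signed)
#' @param state local gas state: list/row with `T` (K), `rho` (kg/m^3),
#'   `a` (m/s)
#' @param d_p particle diameter, m
#' @param gas a [gas_properties()]
#' @param t_wall particle surface temperature, K; NULL means equal to the
#'   local gas temperature
#' @return drag force, N (signed, same sign as `v_rel`)
#' @export
henderson_drag <- function(v_rel, state, d_p, gas = gas_properties(),
                           t_wall = NULL) {
  if (state$rho <= 0 || v_rel == 0) return(0)
  sp <- abs(v_rel)
  Tg <- state$T
  Tw <- if (is.null(t_wall)) Tg else t_wall
  mu <- gas_viscosity(gas, Tg)
  Re <- state$rho * sp * d_p / mu
  Ma <- sp / state$a
  g <- gas$gamma
  S_of <- function(M) M * sqrt(g / 2)
  cd_sub <- function(M, Re) {
    S <- S_of(M)
    tr <- Tw / Tg
    t1 <- 24 / (Re + S * (4.33 + (3.65 - 1.53 * tr) / (1 + 0.353 * tr) *
                            exp(-0.247 * Re / S)))
    t2 <- exp(-0.5 * M / sqrt(Re)) *
      ((4.5 + 0.38 * (0.03 * Re + 0.48 * sqrt(Re))) /
         (1 + 0.03 * Re + 0.48 * sqrt(Re)) + 0.1 * M^2 + 0.2 * M^8)
    t3 <- (1 - exp(-M / Re)) * 0.6 * S
    t1 + t2 + t3
  }
  cd_sup <- function(M, Re) {
    S <- S_of(M)
    num <- 0.9 + 0.34 / M^2 +
      1.86 * sqrt(M / Re) * (2 + 2 / S^2 + 1.058 * sqrt(Tw / Tg) / S -
                               1 / S^4)
    num / (1 + 1.86 * sqrt(M / Re))
  }
  Cd <- if (Ma <= 1) {
    cd_sub(Ma, Re)
  } else if (Ma >= 1.75) {
    cd_sup(Ma, Re)
  } else {
    c1 <- cd_sub(1, Re); c2 <- cd_sup(1.75, Re)
    c1 + 4 / 3 * (Ma - 1) * (c2 - c1)
  }
  sign(v_rel) * 0.5 * state$rho * Cd * pi * (d_p / 2)^2 * sp^2
}

#' Propagate a particle through the jet flow field
#'
#' Integrates the one-dimensional equation of motion
#' `m dv/dx = F_drag(v_gas(x) - v) / v` along the jet axis with an
#' adaptive-step solver, returning the velocity profile and the terminal
#' (end-of-range) velocity. The initial velocity must be positive (the
#' equation is singular at v = 0).
#'
#' @param flow a [jet_flow_field()]
#' @param d_p_nm particle diameter, nm
#' @param rho_p particle mass density, kg/m^3
#' @param v0 initial particle velocity at `x_start_mm`, m/s (> 0)
#' @param x_start_mm,x_end_mm integration range, mm; the start defaults to
#'   the validity bound of the Mach correlation
#' @param n_out number of output samples
#' @param rtol relative tolerance of the adaptive integrator
#' @param t_wall particle surface temperature passed to [henderson_drag()]
#' @return data.frame with columns x_mm, v (particle, m/s), v_gas, M, T, p,
#'   rho; attribute `terminal_velocity`
#' @export
propagate_particle <- function(flow, d_p_nm, rho_p = 1050, v0 = 5,
                               x_start_mm = NULL, x_end_mm = 30,
                               n_out = 200, rtol = 1e-8, t_wall = NULL) {
  if (v0 <= 0) stop("initial velocity must be positive")
  if (is.null(x_start_mm)) x_start_mm <- flow$x_min_mm
  stopifnot(x_end_mm > x_start_mm)
  d_p <- nm_to_m(d_p_nm)
  m_p <- rho_p * pi / 6 * d_p^3
  # scalar fast path equivalent to flow$state_at(), avoiding per-step
  # data.frame construction in the ODE right-hand side
  gas <- flow$gas
  g <- gas$gamma
  p0 <- mbar_to_pa(flow$entrance_pressure)
  T0 <- flow$T0
  rho0 <- p0 * gas$molar_mass / (.R_GAS * T0)
  local_state <- function(x_mm) {
    M <- mach_centerline(x_mm, flow$d_eff_mm, g)
    Tr <- 1 / (1 + (g - 1) / 2 * M^2)
    T_loc <- T0 * Tr
    a <- sqrt(g * .R_GAS * T_loc / gas$molar_mass)
    list(M = M, T = T_loc, p = p0 * Tr^(g / (g - 1)),
         rho = rho0 * Tr^(1 / (g - 1)), a = a, v = M * a)
  }
  deriv <- function(x_m, y, parms) {
    st <- local_state(x_m * 1e3)
    f <- henderson_drag(st$v - y[1], st, d_p, gas, t_wall)
    list(f / (m_p * y[1]))
  }
  xs <- seq(mm_to_m(x_start_mm), mm_to_m(x_end_mm), length.out = n_out)
  sol <- deSolve::ode(y = c(v = v0), times = xs, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = 1e-10)
  if (attr(sol, "istate")[1] < 0)
    stop("particle propagation did not converge; istate = ",
         attr(sol, "istate")[1])
  st <- flow$state_at(sol[, "time"] * 1e3)
  out <- data.frame(x_mm = sol[, "time"] * 1e3, v = sol[, "v"],
                    v_gas = st$v, M = st$M, T = st$T, p = st$p,
                    rho = st$rho)
  attr(out, "terminal_velocity") <- out$v[nrow(out)]
  out
}

#' Terminal particle velocity for given operating conditions
#'
#' Convenience wrapper: builds the flow field for an entrance pressure and
#' propagates a particle to the end of the integration range.
#'
#' @inheritParams propagate_particle
#' @param entrance_pressure mbar
#' @param gas,geometry,T0 as in [jet_flow_field()]
#' @return terminal velocity, m/s
#' @export
jet_terminal_velocity <- function(entrance_pressure, d_p_nm,
                                  rho_p = 1050, v0 = 5, x_end_mm = 30,
                                  gas = gas_properties(),
                                  geometry = injector_geometry(),
                                  T0 = 293.15, rtol = 1e-8) {
  flow <- jet_flow_field(entrance_pressure, gas, geometry, T0)
  prof <- propagate_particle(flow, d_p_nm, rho_p, v0,
                             x_end_mm = x_end_mm, rtol = rtol)
  attr(prof, "terminal_velocity")
}

#' Mean free path of the gas
#'
#' `lambda = (mu / p) sqrt(pi R_s T / 2)` with `R_s` the specific gas
#' constant.
#'
#' @param gas a [gas_properties()]
#' @param T_k temperature, K
#' @param p_pa pressure, Pa
#' @return mean free path, m
#' @export
mean_free_path <- function(gas, T_k, p_pa) {
  Rs <- .R_GAS / gas$molar_mass
  gas_viscosity(gas, T_k) / p_pa * sqrt(pi * Rs * T_k / 2)
}

#' Cunningham slip correction
#'
#' `C_c = 1 + Kn (1.257 + 0.4 exp(-1.1 / Kn))`, the non-continuum drag
#' correction entering the particle relaxation time.
#'
#' @param Kn particle Knudsen number, `2 lambda / d_p`
#' @return slip correction factor (>= 1)
#' @export
cunningham_slip <- function(Kn) {
  stopifnot(all(Kn > 0))
  1 + Kn * (1.257 + 0.4 * exp(-1.1 / Kn))
}

#' Stokes number of a particle at the lens exit orifice
#'
#' `St = tau u / (d_f / 2)` with the relaxation time
#' `tau = C_c rho_p d_p^2 / (18 mu)` and the average orifice flow velocity
#' `u = 4 F_m / (rho_l pi d_f^2)`. This is the dimensionless parameter that
#' governs aerodynamic focusing and acceleration.
#'
#' @param C_c slip correction (dimensionless)
#' @param rho_p particle density, kg/m^3
#' @param d_p particle diameter, m
#' @param mu gas dynamic viscosity, Pa s
#' @param F_m gas mass flow rate, kg/s
#' @param rho_l gas density at the orifice, kg/m^3
#' @param d_f orifice diameter, m
#' @return Stokes number (dimensionless)
#' @export
stokes_number <- function(C_c, rho_p, d_p, mu, F_m, rho_l, d_f) {
  stopifnot(C_c > 0, rho_p > 0, d_p > 0, mu > 0, F_m > 0, rho_l > 0,
            d_f > 0)
  tau <- C_c * rho_p * d_p^2 / (18 * mu)
  u <- 4 * F_m / (rho_l * pi * d_f^2)
  tau * u / (d_f / 2)
}

#' Stokes number for operating conditions
#'
#' Evaluates [stokes_number()] with the orifice flow quantities from the
#' isentropic choked-orifice estimate and the slip correction at the sonic
#' orifice state.
#'
#' @param entrance_pressure mbar
#' @param d_p_nm particle diameter, nm
#' @param rho_p particle density, kg/m^3
#' @param gas,geometry,T0 as in [jet_flow_field()]
#' @return Stokes number
#' @export
stokes_number_for_conditions <- function(entrance_pressure, d_p_nm,
                                         rho_p = 1050,
                                         gas = gas_properties(),
                                         geometry = injector_geometry(),
                                         T0 = 293.15) {
  of <- orifice_flow(entrance_pressure, gas, geometry, T0)
  d_p <- nm_to_m(d_p_nm)
  lam <- mean_free_path(gas, of$state$T, of$state$p)
  C_c <- cunningham_slip(2 * lam / d_p)
  stokes_number(C_c, rho_p, d_p, gas_viscosity(gas, of$state$T),
                of$F_m, of$rho_l, mm_to_m(geometry$orifice_diameter))
}

#' Default velocity-collapse model form
#'
#' Saturating relation between the normalized terminal velocity and the
#' Stokes number: `v/c = B + (A - B) C St / (1 + C St)`. B is the low-St
#' floor, A the high-St asymptote, 1/C the transition Stokes number. The
#' fit routine accepts any alternative form.
#'
#' @param St Stokes number
#' @param A,B,C parameters
#' @return v/c
#' @export
collapse_model_default <- function(St, A, B, C) {
  B + (A - B) * C * St / (1 + C * St)
}

#' Fit the terminal-velocity vs Stokes-number collapse
#'
#' Nonlinear least squares of normalized terminal velocities against Stokes
#' numbers using a pluggable three-parameter model form (default
#' [collapse_model_default()]).
#'
#' @param St Stokes numbers (> 0, >= 5 points)
#' @param v_over_c terminal velocities normalized by the speed of sound
#' @param model function(St, A, B, C)
#' @param start named list/vector of starting values for A, B, C
#' @return object of class `velocity_fit`: `A`, `B`, `C`, `residuals`,
#'   `model`, `fit`
#' @export
fit_velocity_collapse <- function(St, v_over_c,
                                  model = collapse_model_default,
                                  start = c(A = 0.5, B = 0.01, C = 0.1)) {
  stopifnot(length(St) >= 5, all(St > 0), length(St) == length(v_over_c))
  df <- data.frame(St = St, y = v_over_c)
  fit <- minpack.lm::nlsLM(y ~ model(St, A, B, C), data = df,
                           start = as.list(start),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  structure(list(A = unname(cf["A"]), B = unname(cf["B"]),
                 C = unname(cf["C"]),
                 residuals = stats::resid(fit), model = model, fit = fit),
            class = "velocity_fit")
}

#' Fit entrance velocity and effective orifice diameter to measured speeds
#'
#' Joint least squares over the drag model: for each operating condition
#' (entrance pressure and particle diameter) the particle entrance velocity
#' is free, and one global effective-to-physical orifice diameter ratio is
#' shared by all conditions. Measured `(x, v)` samples are compared with
#' [propagate_particle()] profiles.
#'
#' @param data data.frame with columns `pressure` (mbar), `diameter` (nm),
#'   `x` (mm), `v` (m/s) and optionally `rho_p` (kg/m^3, default 1050)
#' @param ratio_start starting value for the diameter ratio
#' @param v0_start starting entrance velocity, m/s
#' @param gas a [gas_properties()]
#' @param orifice_diameter physical orifice diameter, mm
#' @param rtol propagation tolerance (looser than default for fitting speed)
#' @param maxit optimizer iteration cap
#' @return list: `effective_diameter_ratio`, `entrance_velocities` (named by
#'   condition), `sse`, `convergence`
#' @export
fit_entrance_parameters <- function(data, ratio_start = 0.9, v0_start = 5,
                                    gas = gas_properties(),
                                    orifice_diameter = 1.5,
                                    rtol = 1e-6, maxit = 200) {
  stopifnot(all(c("pressure", "diameter", "x", "v") %in% names(data)))
  if (!"rho_p" %in% names(data)) data$rho_p <- 1050
  cond <- unique(data[, c("pressure", "diameter", "rho_p")])
  if (any(table(interaction(data$pressure, data$diameter)) < 2))
    stop("need at least 2 distances per condition")
  nc <- nrow(cond)
  obj <- function(par) {
    ratio <- stats::plogis(par[1])  # keep ratio in (0, 1)
    v0s <- exp(par[-1])
    sse <- 0
    for (i in seq_len(nc)) {
      sel <- data$pressure == cond$pressure[i] &
             data$diameter == cond$diameter[i]
      geom <- injector_geometry(orifice_diameter, ratio)
      flow <- jet_flow_field(cond$pressure[i], gas, geom)
      xe <- max(data$x[sel])
      prof <- propagate_particle(flow, cond$diameter[i], cond$rho_p[i],
                                 v0 = v0s[i], x_end_mm = xe + 1e-6,
                                 n_out = 64, rtol = rtol)
      vhat <- stats::approx(prof$x_mm, prof$v, xout = data$x[sel],
                            rule = 2)$y
      sse <- sse + sum((vhat - data$v[sel])^2)
    }
    sse
  }
  par0 <- c(stats::qlogis(ratio_start), rep(log(v0_start), nc))
  opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  ev <- exp(opt$par[-1])
  names(ev) <- paste0("p", cond$pressure, "_d", cond$diameter)
  list(effective_diameter_ratio = stats::plogis(opt$par[1]),
       entrance_velocities = ev,
       sse = opt$value, convergence = opt$convergence)
}
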