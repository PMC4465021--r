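# Independent closed-form references and small finite-volume benchmark
# problems used to verify the solver before trusting the bottle runs.

#' Analytic transient slab conduction profile
#'
#' Fourier series solution for a slab of half-thickness `L`, initially at
#' `T_init`, whose two walls are stepped to `T_wall` at `t = 0`:
#' `T(x,t) = T_wall + (T_init - T_wall) * sum_k (4/((2k+1)pi)) (-1)^k
#'   cos((2k+1) pi x / (2L)) exp(-((2k+1) pi / (2L))^2 alpha t)`.
#'
#' @param problem list with `L` (half-thickness, m), `alpha` (m^2/s),
#'   `T_init`, `T_wall` (degrees C) and `n` (series terms, default 50).
#' @param x position from the slab centre, `|x| <= L`, in metres
#'   (vectorized).
#' @param t time in seconds.
#' @return Temperature(s) in degrees C.
#' @export
slab_conduction_profile <- function(problem, x, t) {
  L <- problem$L; alpha <- problem$alpha
  n <- if (is.null(problem$n)) 50L else problem$n
  stopifnot(L > 0, alpha > 0, n >= 1, all(abs(x) <= L + 1e-12), t >= 0)
  s <- 0
  for (k in 0:(n - 1)) {
    lam <- (2 * k + 1) * pi / (2 * L)
    s <- s + (4 / ((2 * k + 1) * pi)) * (-1)^k * cos(lam * x) *
      exp(-lam^2 * alpha * t)
  }
  problem$T_wall + (problem$T_init - problem$T_wall) * s
}

#' Lumped-capacitance cooling/heating curve
#'
#' Closed-form temperature of a body whose interior is effectively
#' isothermal (Biot number << 1), exchanging heat with an environment by
#' Newton cooling: `T(t) = T_env + (T_init - T_env) exp(-h A t /
#' (rho cp V))`.
#'
#' @param t time in seconds (vectorized).
#' @param h heat-transfer coefficient, W/(m^2 K).
#' @param A exchange surface area, m^2.
#' @param rho density, kg/m^3.
#' @param cp specific heat, J/(kg K).
#' @param V body volume, m^3.
#' @param T_init,T_env initial and environment temperatures, degrees C.
#' @return Temperature(s) in degrees C.
#' @export
lumped_capacitance_temperature <- function(t, h, A, rho, cp, V, T_init, T_env) {
  stopifnot(h > 0, A > 0, rho > 0, cp > 0, V > 0)
  T_env + (T_init - T_env) * exp(-h * A * t / (rho * cp * V))
}

# Minimal hand-built grid for benchmark problems: a single material on an
# nr x nz grid with per-side thermal boundary codes.
manual_grid <- function(redge, zedge, mat,
                        bcW = 1, bcE = 1, bcS = 1, bcN = 1,
                        vW = c(0, 0), vE = c(0, 0), vS = c(0, 0), vN = c(0, 0),
                        phase = 0L) {
  nr <- length(redge) - 1L; nz <- length(zedge) - 1L
  bcth <- array(0L, c(nr, nz, 4)); bv1 <- array(0, c(nr, nz, 4))
  bv2 <- array(0, c(nr, nz, 4)); fbc <- array(1L, c(nr, nz, 4))
  set_side <- function(d, idx_i, idx_j, code, v) {
    bcth[idx_i, idx_j, d] <<- as.integer(code)
    bv1[idx_i, idx_j, d] <<- v[1]; bv2[idx_i, idx_j, d] <<- v[2]
  }
  set_side(1, 1, seq_len(nz), bcW, vW)
  set_side(2, nr, seq_len(nz), bcE, vE)
  set_side(3, seq_len(nr), 1, bcS, vS)
  set_side(4, seq_len(nr), nz, bcN, vN)
  list(nr = nr, nz = nz, redge = redge, zedge = zedge,
       region = matrix(0L, nr, nz),
       mat_rho = mat$rho, mat_cp = mat$cp, mat_k = mat$k,
       mat_beta = if (is.na(mat$beta)) 0 else mat$beta,
       mat_mu = if (is.na(mat$mu)) 0 else mat$mu,
       mat_T0 = 0,
       mat_phase = as.integer(phase),
       mat_grp = if (phase == 1L) 1L else 0L,
       bcth = bcth, bv1 = bv1, bv2 = bv2, fbc = fbc, gmag = 9.81)
}

manual_state <- function(nr, nz, T0) {
  z <- matrix(0, nr, nz)
  list(T = matrix(T0, nr, nz), ur = z, uz = z, p = z,
       T_prev = matrix(T0, nr, nz), ur_prev = z, uz_prev = z,
       Fe = z, Fn = z, step = 0L, time = 0)
}

run_manual <- function(grid, state, nsteps, dt, flow = FALSE,
                       options = solver_options(dt = dt, flow = flow)) {
  options$dt <- dt; options$flow <- flow
  core_advance(grid, state, opts_for_core(options), as.integer(nsteps))
}

#' Finite-volume slab conduction benchmark
#'
#' Runs the flow-disabled solver on a 1-D slab (resolved along z) with both
#' walls stepped to `T_wall`, for comparison against
#' [slab_conduction_profile()].
#'
#' @param n number of cells across the slab.
#' @param L slab half-thickness, m.
#' @param material a [material()] object.
#' @param T_init,T_wall initial and wall temperatures, degrees C.
#' @param t_end end time, s.
#' @param dt time step, s.
#' @return data.frame with `x` (position from slab centre, m), `T_fv`
#'   (numeric solution) and `T_exact` (series solution, 50 terms).
#' @export
slab_fv_profile <- function(n, L, material, T_init, T_wall, t_end, dt) {
  zedge <- seq(0, 2 * L, length.out = n + 1)
  g <- manual_grid(redge = c(0.01, 0.02), zedge = zedge, mat = material,
                   bcS = 2, bcN = 2, vS = c(T_wall, 0), vN = c(T_wall, 0))
  st <- manual_state(1, n, T_init)
  nst <- round(t_end / dt)
  st <- run_manual(g, st, nst, dt)
  zc <- (zedge[-1] + zedge[-(n + 1)]) / 2
  x <- zc - L
  alpha <- thermal_diffusivity(material)
  data.frame(x = x, T_fv = as.numeric(st$T),
             T_exact = slab_conduction_profile(
               list(L = L, alpha = alpha, T_init = T_init,
                    T_wall = T_wall, n = 50L), x, nst * dt))
}

#' Finite-volume lumped-capacitance benchmark
#'
#' A small solid cylinder of high-conductivity material (Biot << 1) with a
#' convective boundary on all exterior surfaces, for comparison against
#' [lumped_capacitance_temperature()].
#'
#' @param times sample times, s (multiples of `dt`).
#' @param R,H cylinder radius and height, m.
#' @param mat a solid [material()]; defaults to a high-conductivity body so
#'   that the Biot number stays far below 0.01.
#' @param h heat-transfer coefficient, W/(m^2 K).
#' @param T_init,T_env initial and environment temperatures, degrees C.
#' @param dt time step, s.
#' @param n cells per direction.
#' @return data.frame with `time`, `T_fv` (volume-mean numeric solution)
#'   and `T_exact`.
#' @export
lumped_fv_temperature <- function(times, R = 0.004, H = 0.008,
                                  mat = material("conductor", rho = 2700,
                                    cp = 900, k = 200, phase = "solid"),
                                  h = 10.45, T_init = 4, T_env = 80,
                                  dt = 1, n = 8) {
  redge <- seq(0, R, length.out = n + 1)
  zedge <- seq(0, H, length.out = n + 1)
  g <- manual_grid(redge, zedge, mat,
                   bcW = 1, bcE = 3, bcS = 3, bcN = 3,
                   vE = c(h, T_env), vS = c(h, T_env), vN = c(h, T_env))
  st <- manual_state(n, n, T_init)
  dr <- diff(redge); rc <- (redge[-1] + redge[-(n + 1)]) / 2
  vols <- outer(2 * pi * rc * dr, diff(zedge))
  A <- 2 * pi * R * H + 2 * pi * R^2
  V <- pi * R^2 * H
  times <- sort(times)
  out <- data.frame(time = times, T_fv = NA_real_,
                    T_exact = lumped_capacitance_temperature(
                      times, h, A, mat$rho, mat$cp, V,
                      T_init, T_env))
  tprev <- 0
  for (k in seq_along(times)) {
    nst <- round((times[k] - tprev) / dt)
    if (nst > 0) st <- run_manual(g, st, nst, dt)
    tprev <- tprev + nst * dt
    out$T_fv[k] <- sum(vols * st$T) / sum(vols)
  }
  out
}

#' Refined reference run
#'
#' Re-runs a scenario with `refinement_factor^2` times the cells and the
#' time step divided by `refinement_factor`; serves as the brute-force
#' reference for space/time convergence assertions.
#'
#' @param scenario a `"warming_scenario"`.
#' @param options base solver options.
#' @param refinement_factor integer >= 1.
#' @param end_time,sample_interval as in [simulate_warming()].
#' @param target_cells base resolution.
#' @return A `"warming_run"` at the refined resolution.
#' @export
refined_reference_metrics <- function(scenario, options, refinement_factor,
                                      end_time, sample_interval = 10,
                                      target_cells = 4300) {
  stopifnot(refinement_factor >= 1)
  opts <- options
  opts$dt <- options$dt / refinement_factor
  simulate_warming(scenario, opts, end_time = end_time,
                   sample_interval = sample_interval,
                   target_cells = round(target_cells * refinement_factor^2))
}

#' Run the verification oracle suite
#'
#' Exercises the solver against the closed-form references: transient slab
#' conduction (L2 error and observed convergence order), the
#' lumped-capacitance limit, and the circulation direction in a
#' differentially heated cavity.
#'
#' @param quiet suppress the printed table.
#' @return data.frame with columns `check`, `value`, `threshold`, `pass`.
#' @export
run_verification <- function(quiet = FALSE) {
  milk <- make_material_table()$milk
  alpha <- thermal_diffusivity(milk)
  L <- 0.01
  t_end <- 0.2 * L^2 / alpha
  l2err <- function(n, dt) {
    pr <- slab_fv_profile(n, L, milk, 4, 80, t_end, dt)
    sqrt(mean((pr$T_fv - pr$T_exact)^2)) / (80 - 4)
  }
  e200 <- l2err(200, t_end / 4000)
  ns <- c(25, 50, 100)
  errs <- vapply(ns, function(n) l2err(n, t_end / (40 * n)), 0)
  order_obs <- min(diff(-log(errs)) / diff(log(ns)))

  lf <- lumped_fv_temperature(times = c(600, 1800, 3600))
  lerr <- max(abs(lf$T_fv - lf$T_exact) / abs(80 - lf$T_exact + 1e-9))

  circ <- cavity_circulation_check()

  res <- data.frame(
    check = c("slab conduction L2 error (200 cells)",
              "slab spatial convergence order",
              "lumped capacitance max rel error",
              "heated-cavity circulation (up at hot wall)"),
    value = c(e200, order_obs, lerr, as.numeric(circ)),
    threshold = c(0.01, 1.8, 0.02, 1),
    pass = c(e200 < 0.01, order_obs >= 1.8, lerr < 0.02, circ))
  if (!quiet) print(res, digits = 3)
  invisible(res)
}

# Differentially heated closed cavity: hot inner wall, cold outer wall.
# Buoyancy must drive the fluid upward along the hot wall.
cavity_circulation_check <- function() {
  water <- make_material_table()$water
  n <- 16
  redge <- seq(0.1, 0.12, length.out = n + 1)   # large radius ~ planar slot
  zedge <- seq(0, 0.02, length.out = n + 1)
  g <- manual_grid(redge, zedge, water,
                   bcW = 2, bcE = 2, bcS = 1, bcN = 1,
                   vW = c(60, 0), vE = c(20, 0), phase = 1L)
  g$mat_T0 <- 40
  st <- manual_state(n, n, 40)
  opts <- solver_options(dt = 0.05, flow = TRUE, on_nonconverge = "warn")
  st <- run_manual(g, st, 40, opts$dt, flow = TRUE, options = opts)
  uz_hot <- mean(st$uz[1:2, ])
  uz_cold <- mean(st$uz[(n - 1):n, ])
  uz_hot > 0 && uz_cold < 0
}
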