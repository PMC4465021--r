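# Time integration of the coupled temperature/flow fields.
#
# The energy equation is solved on every active cell; the incompressible
# Boussinesq Navier-Stokes equations are solved in the fluid regions only
# (bath water, milk and headspace air form three separate lidded fluid
# groups that exchange heat but not mass).

#' Solver options
#'
#' @param dt time step in seconds.
#' @param scheme `"bdf2"` (second-order implicit, backward Euler on the
#'   first step) or `"be"` (backward Euler throughout).
#' @param advection advection scheme; `"upwind1"` (first-order upwind, the
#'   default, which guarantees bounded temperatures).
#' @param tol relative outer-iteration residual tolerance.
#' @param max_outer maximum outer (flow/energy coupling) iterations per
#'   step.  The segregated iteration contracts geometrically; refined
#'   meshes contract more slowly and can need well over 50 iterations
#'   during the start-up transient, so the ceiling is generous.
#' @param relax_u,relax_p,relax_T under-relaxation factors for momentum,
#'   pressure and energy.
#' @param t_ref optional named list of Boussinesq reference temperatures per
#'   fluid region (degrees C); defaults to each fluid's initial temperature.
#' @param air_flow solve buoyant flow in the headspace air (`TRUE`, default)
#'   or treat the headspace as conduction-only.
#' @param flow master switch for the flow solver; `FALSE` gives pure
#'   conduction everywhere (used by the verification oracles).
#' @param tol_energy relative residual tolerance of the energy solve that
#'   commits each step.
#' @param tol_energy_outer looser energy tolerance used inside the outer
#'   coupling iterations (a tight solve always finishes the step).
#' @param div_tol scaled discrete-divergence tolerance enforced by the
#'   pressure-correction solve.
#' @param max_cg maximum pressure-correction CG iterations in the
#'   step-finishing solve.
#' @param cg_relred relative residual reduction requested from the
#'   pressure-correction solve inside outer iterations.
#' @param cg_max_inner CG iteration cap inside outer iterations.
#' @param mom_sweeps TDMA sweeps per momentum solve.
#' @param max_energy_sweeps cap on TDMA sweeps for the energy solve.
#' @param cfl_warn advective Courant number above which a warning is
#'   recorded in the step diagnostics.
#' @param on_nonconverge `"error"` (default) or `"warn"` when the outer
#'   iteration fails to reach `tol` within `max_outer`.
#' @return A list of class `"solver_options"`.
#' @export
solver_options <- function(dt = 0.1, scheme = c("bdf2", "be"),
                           advection = c("upwind1"),
                           tol = 1e-5, max_outer = 200,
                           relax_u = 0.7, relax_p = 0.3, relax_T = 1.0,
                           t_ref = NULL, air_flow = TRUE, flow = TRUE,
                           tol_energy = 1e-12, tol_energy_outer = 1e-7,
                           div_tol = 1e-6, max_cg = 2000, cg_relred = 0.05,
                           cg_max_inner = 60, mom_sweeps = 2,
                           max_energy_sweeps = 1000, cfl_warn = 25,
                           on_nonconverge = c("error", "warn")) {
  scheme <- match.arg(scheme)
  advection <- match.arg(advection)
  on_nonconverge <- match.arg(on_nonconverge)
  stopifnot(dt > 0, tol > 0, tol_energy > 0, div_tol > 0,
            relax_u > 0, relax_u <= 1, relax_p > 0, relax_p <= 1,
            relax_T > 0, relax_T <= 1, max_outer >= 1)
  structure(list(dt = dt, scheme = scheme, advection = advection, tol = tol,
                 max_outer = as.integer(max_outer), relax_u = relax_u,
                 relax_p = relax_p, relax_T = relax_T, t_ref = t_ref,
                 air_flow = air_flow, flow = flow, tol_energy = tol_energy,
                 tol_energy_outer = tol_energy_outer, div_tol = div_tol,
                 max_cg = as.integer(max_cg), cg_relred = cg_relred,
                 cg_max_inner = as.integer(cg_max_inner),
                 mom_sweeps = as.integer(mom_sweeps),
                 max_energy_sweeps = as.integer(max_energy_sweeps),
                 cfl_warn = cfl_warn, on_nonconverge = on_nonconverge),
            class = "solver_options")
}

opts_for_core <- function(options) {
  list(dt = options$dt, bdf2 = options$scheme == "bdf2", tol = options$tol,
       max_outer = options$max_outer, relax_u = options$relax_u,
       relax_p = options$relax_p, relax_T = options$relax_T,
       flow = options$flow, tol_energy = options$tol_energy,
       tol_energy_outer = options$tol_energy_outer,
       div_tol = options$div_tol, max_cg = options$max_cg,
       cg_relred = options$cg_relred, cg_max_inner = options$cg_max_inner,
       mom_sweeps = options$mom_sweeps,
       max_energy_sweeps = options$max_energy_sweeps,
       cfl_warn = options$cfl_warn)
}

# Convert a mesh + scenario + options into the flat grid representation the
# C++ core consumes: 0-based region ids, per-region material vectors,
# thermal and flow boundary codes per cell face.
as_fv_grid <- function(mesh, options = solver_options()) {
  sc <- mesh$scenario
  nr <- mesh$nr; nz <- mesh$nz; ncell <- nr * nz
  nregs <- length(mesh$region_names)
  mats <- mesh$materials
  phase <- vapply(mats, function(m) if (m$phase == "solid") 0L else 1L, 0L)
  if (!isTRUE(options$air_flow)) {
    k <- match("headspace_air", mesh$region_names)
    if (!is.na(k)) phase[k] <- 0L
  }
  grp <- integer(nregs)
  grp[phase == 1L] <- seq_len(sum(phase == 1L))
  T0 <- numeric(nregs)
  for (k in seq_len(nregs)) {
    nm <- mesh$region_names[k]
    T0[k] <- sc$initial_temperatures[[nm]]
    if (!is.null(options$t_ref) && !is.null(options$t_ref[[nm]]))
      T0[k] <- options$t_ref[[nm]]
  }
  bspecs <- sc$boundaries
  names(bspecs) <- vapply(bspecs, `[[`, "", "tag")

  region0 <- mesh$region
  region0[is.na(region0)] <- 0L
  region0 <- region0 - 1L          # -1 = inactive

  bcth <- array(0L, c(nr, nz, 4))
  bv1 <- array(0, c(nr, nz, 4))
  bv2 <- array(0, c(nr, nz, 4))
  fbc <- array(1L, c(nr, nz, 4))
  sides <- c("W", "E", "S", "N")
  bath_id <- match("bath_water", mesh$region_names)
  reg <- mesh$region
  for (j in seq_len(nz)) for (i in seq_len(nr)) {
    if (is.na(reg[i, j])) next
    for (d in 1:4) {
      side <- sides[d]
      ni <- i + (side == "E") - (side == "W")
      nj <- j + (side == "N") - (side == "S")
      ext <- ni < 1 || ni > nr || nj < 1 || nj > nz || is.na(reg[ni, nj])
      if (!ext) {
        # internal face: thermal code 0; flow code from phases/groups
        kP <- reg[i, j]; kN <- reg[ni, nj]
        if (phase[kP] == 1L) {
          if (phase[kN] == 0L) fbc[i, j, d] <- 1L
          else if (grp[kN] == grp[kP]) fbc[i, j, d] <- 0L
          else fbc[i, j, d] <- 2L   # liquid/gas interface: no-shear
        }
        next
      }
      tag <- boundary_tag(mesh, i, j, side, bath_id)
      bs <- bspecs[[tag]]
      if (is.null(bs)) stop("no boundary spec for tag '", tag, "'")
      if (bs$kind == "symmetry_axis") {
        bcth[i, j, d] <- 1L
        fbc[i, j, d] <- 2L
      } else if (bs$kind == "fixed_temperature") {
        bcth[i, j, d] <- 2L; bv1[i, j, d] <- bs$T_wall
        fbc[i, j, d] <- 1L
      } else if (bs$kind == "convective") {
        bcth[i, j, d] <- 3L; bv1[i, j, d] <- bs$h; bv2[i, j, d] <- bs$T_ambient
        fbc[i, j, d] <- 1L
      } else if (bs$kind == "shear_free_interface") {
        bcth[i, j, d] <- 3L; bv1[i, j, d] <- bs$h; bv2[i, j, d] <- bs$T_ambient
        fbc[i, j, d] <- 2L
      } else stop("unknown boundary kind '", bs$kind, "'")
    }
  }
  list(nr = nr, nz = nz, redge = mesh$redge, zedge = mesh$zedge,
       region = region0,
       mat_rho = vapply(mats, `[[`, 0, "rho"),
       mat_cp = vapply(mats, `[[`, 0, "cp"),
       mat_k = vapply(mats, `[[`, 0, "k"),
       mat_beta = ifelse(phase == 1L, vapply(mats, function(m)
         ifelse(is.na(m$beta), 0, m$beta), 0), 0),
       mat_mu = ifelse(phase == 1L, vapply(mats, function(m)
         ifelse(is.na(m$mu), 0, m$mu), 0), 0),
       mat_T0 = T0,
       mat_phase = as.integer(phase), mat_grp = as.integer(grp),
       bcth = bcth, bv1 = bv1, bv2 = bv2, fbc = fbc,
       gmag = sc$gravity)
}

#' Initial field state for a mesh
#'
#' @param mesh an `"aximesh"`.
#' @param options solver options (only `t_ref`/`air_flow` matter here).
#' @return A `"field_state"`: per-cell temperature, velocity components,
#'   pressure, face mass fluxes and time bookkeeping.  Velocities are zero
#'   everywhere (and stay exactly zero in solid cells).
#' @export
init_state <- function(mesh, options = solver_options()) {
  sc <- mesh$scenario
  Tm <- matrix(sc$params$ambient_temperature, mesh$nr, mesh$nz)
  for (k in seq_along(mesh$region_names)) {
    nm <- mesh$region_names[k]
    Tm[mesh$region == k] <- sc$initial_temperatures[[nm]]
  }
  z <- matrix(0, mesh$nr, mesh$nz)
  structure(list(T = Tm, ur = z, uz = z, p = z,
                 T_prev = Tm, ur_prev = z, uz_prev = z,
                 Fe = z, Fn = z, step = 0L, time = 0,
                 diag = NULL),
            class = "field_state")
}

#' Advance the coupled fields in time
#'
#' Runs `nsteps` implicit time steps of the coupled flow/energy system.
#' Each step iterates momentum, pressure-correction and energy solves until
#' the combined residuals fall below the outer tolerance.
#'
#' @param state a `"field_state"`.
#' @param mesh an `"aximesh"` (or a prebuilt fv grid via the `grid`
#'   argument).
#' @param options solver options.
#' @param nsteps number of time steps.
#' @param grid optional precomputed grid (from repeated calls); built from
#'   `mesh` when `NULL`.
#' @return Updated `"field_state"`; its `diag` entry carries last-step
#'   residuals and Courant diagnostics.
#' @export
advance <- function(state, mesh, options = solver_options(), nsteps = 1,
                    grid = NULL) {
  if (is.null(grid)) grid <- as_fv_grid(mesh, options)
  out <- core_advance(grid, state, opts_for_core(options), as.integer(nsteps))
  out$step <- as.integer(out$step)
  class(out) <- "field_state"
  if (!isTRUE(out$diag$converged)) {
    msg <- sprintf(paste0("outer iteration did not converge at t=%.3f s: ",
                          "du=%.3g dT=%.3g div=%.3g after %d iterations"),
                   out$time, out$diag$du, out$diag$dT, out$diag$div_scaled,
                   out$diag$outer_iters)
    if (identical(options$on_nonconverge, "warn")) warning(msg)
    else stop(msg)
  }
  out
}

#' Simulate bottle warming
#'
#' Builds the mesh, initializes all fields and advances the coupled
#' conjugate heat-transfer / natural-convection solver from the initial
#' state to `end_time`, recording milk metrics every `sample_interval`
#' seconds.  The heater boundaries are held at the bath temperature for the
#' whole run.
#'
#' @param scenario a `"warming_scenario"`.
#' @param options solver options, see [solver_options()].
#' @param end_time simulated end time in seconds.
#' @param sample_interval metrics sampling interval in seconds.
#' @param target_cells mesh resolution, see [build_mesh()].
#' @param snapshot_times times (s) at which to keep full field snapshots.
#' @param mesh optional prebuilt mesh (overrides `target_cells`).
#' @param region region the metrics are computed over (default `"milk"`).
#' @return A `"warming_run"`: `metrics` (data.frame with columns `time_s`,
#'   `pat_C`, `frac_above_40`, `t_min_C`, `t_max_C`), `snapshots` (named
#'   list of field states), the final `state`, `mesh`, `scenario` and
#'   `options`.
#' @examples
#' \donttest{
#' run <- simulate_warming(bottle_scenario("bottle1"),
#'                         solver_options(dt = 0.2), end_time = 30,
#'                         sample_interval = 10, target_cells = 1200)
#' run$metrics
#' }
#' @export
simulate_warming <- function(scenario, options = solver_options(),
                             end_time, sample_interval = 10,
                             target_cells = 4300,
                             snapshot_times = numeric(0), mesh = NULL,
                             region = "milk") {
  stopifnot(end_time >= 0, sample_interval > 0)
  if (is.null(mesh)) mesh <- build_mesh(scenario, target_cells)
  grid <- as_fv_grid(mesh, options)
  state <- init_state(mesh, options)

  sample_t <- seq(0, end_time, by = sample_interval)
  if (end_time > 0 && utils::tail(sample_t, 1) < end_time - 1e-9)
    sample_t <- c(sample_t, end_time)
  snapshot_times <- sort(unique(snapshot_times))
  stops <- sort(unique(signif(c(sample_t, snapshot_times), 12)))
  stops <- stops[stops <= end_time + 1e-9]

  rows <- list()
  snaps <- list()
  take <- function(state, t) {
    if (any(abs(sample_t - t) < 1e-9)) {
      rec <- metrics_record(state, mesh, region)
      rec$time_s <- t      # nominal sample time, free of dt round-off drift
      rows[[length(rows) + 1L]] <<- rec
    }
    if (any(abs(snapshot_times - t) < 1e-9))
      snaps[[sprintf("t%g", t)]] <<- state
  }
  take(state, 0)
  tprev <- 0
  t_range <- range(state$T[!is.na(mesh$region)])
  for (tk in stops[stops > 1e-12]) {
    nst <- round((tk - tprev) / options$dt)
    if (nst > 0) {
      state <- advance(state, mesh, options, nst, grid = grid)
      t_range <- range(t_range, state$diag$T_min_seen, state$diag$T_max_seen)
    }
    tprev <- tprev + nst * options$dt
    take(state, tk)
  }
  metrics <- do.call(rbind, rows)
  structure(list(metrics = metrics, snapshots = snaps, state = state,
                 mesh = mesh, scenario = scenario, options = options,
                 t_range_seen = t_range),
            class = "warming_run")
}

#' @export
print.warming_run <- function(x, ...) {
  n <- nrow(x$metrics)
  cat(sprintf("<warming_run> %d samples to t=%g s\n", n,
              x$metrics$time_s[n]))
  last <- x$metrics[n, ]
  cat(sprintf("  final milk: PAT %.1f C, min %.1f C, max %.1f C, %.0f%% above 40 C\n",
              last$pat_C, last$t_min_C, last$t_max_C,
              100 * last$frac_above_40))
  invisible(x)
}

#' Plot milk temperature history of a run
#'
#' @param x a `"warming_run"`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.warming_run <- function(x, ...) {
  m <- x$metrics
  graphics::matplot(m$time_s, cbind(m$pat_C, m$t_min_C, m$t_max_C),
                    type = "l", lty = c(1, 2, 2), col = c(1, 4, 2),
                    xlab = "time (s)", ylab = "milk temperature (C)", ...)
  graphics::abline(h = 40, col = "grey", lty = 3)
  graphics::legend("bottomright", c("mass-weighted mean", "min", "max"),
                   lty = c(1, 2, 2), col = c(1, 4, 2), bty = "n")
  invisible(x)
}
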