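# Shared fixtures.  Small, fast configurations for the unit tests; the
# full-resolution runs used by the acceptance checks are built lazily and
# cached so several test blocks can share them.

.run_cache <- new.env(parent = emptyenv())

# quick options for unit tests (coarse but physically meaningful)
quick_options <- function(...) {
  solver_options(dt = 0.2, ...)
}

# a small bottle scenario meshed coarsely
quick_mesh <- function(preset = "bottle1", cells = 700) {
  key <- sprintf("mesh_%s_%d", preset, cells)
  if (is.null(.run_cache[[key]]))
    .run_cache[[key]] <- build_mesh(bottle_scenario(preset), cells)
  .run_cache[[key]]
}

# Full-resolution runs at the reference problem sizes (about 4300 cells,
# dt = 0.1 s), shared by the acceptance tests.
reference_run <- function(preset) {
  key <- paste0("paper_", preset)
  if (is.null(.run_cache[[key]])) {
    if (preset == "bottle1") {
      .run_cache[[key]] <- simulate_warming(
        bottle_scenario("bottle1"), solver_options(dt = 0.1),
        end_time = 420, sample_interval = 10, target_cells = 4300,
        snapshot_times = c(150, 180, 420))
    } else {
      .run_cache[[key]] <- simulate_warming(
        bottle_scenario("bottle2"), solver_options(dt = 0.1),
        end_time = 600, sample_interval = 10, target_cells = 4300,
        snapshot_times = c(300, 420, 600))
    }
  }
  .run_cache[[key]]
}

# synthetic field state with prescribed temperatures on a mesh
# (Tfun may return a scalar or a vector; recycling handles both)
fake_state <- function(mesh, Tfun) {
  st <- init_state(mesh)
  rc <- (mesh$redge[-1] + mesh$redge[-length(mesh$redge)]) / 2
  zc <- (mesh$zedge[-1] + mesh$zedge[-length(mesh$zedge)]) / 2
  rg <- rep(rc, times = length(zc))
  zg <- rep(zc, each = length(rc))
  st$T <- matrix(Tfun(rg, zg) + 0 * rg, mesh$nr, mesh$nz)
  st
}
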