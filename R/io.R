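# Configuration parsing, result serialization and snapshot output.

log_levels <- c(debug = 1, info = 2, warning = 3, error = 4)

mw_log <- function(level, ...) {
  lv <- getOption("milkwarm.log_level", "info")
  if (log_levels[[level]] >= log_levels[[lv]])
    message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
  invisible(NULL)
}

scenario_keys <- c("preset", "milk_volume_ml", "total_volume_ml", "height_mm",
                   "wall_mm", "gap_mm", "bath_above_milk_mm", "cap_mm",
                   "bath_temperature", "initial_temperature",
                   "ambient_temperature", "h_ambient", "gravity", "materials")
solver_keys <- c("dt", "scheme", "advection", "tol", "max_outer", "relax_u",
                 "relax_p", "relax_T", "t_ref", "air_flow", "flow",
                 "tol_energy", "tol_energy_outer", "div_tol", "max_cg",
                 "cg_relred", "cg_max_inner", "mom_sweeps",
                 "max_energy_sweeps", "cfl_warn", "on_nonconverge")
run_keys <- c("end_time", "sample_interval", "out_dir", "snapshot_interval",
              "log_level", "target_cells")

check_keys <- function(x, allowed, path) {
  bad <- setdiff(names(x), allowed)
  if (length(bad) > 0)
    stop("unknown configuration key(s) at ", path, ": ",
         paste0(path, ".", bad, collapse = ", "))
  invisible(x)
}

#' Load a run configuration
#'
#' Reads a YAML run configuration with sections `scenario` (a preset name
#' or inline cylinder-scenario parameters, with optional material
#' overrides), `solver` ([solver_options()] fields) and `run` (`end_time`,
#' `sample_interval`, `out_dir`, `snapshot_interval`, `target_cells`,
#' `log_level`).  Unknown keys are rejected with their key path.
#'
#' @param path path to the YAML file.
#' @return A validated `"run_config"`: list with `scenario`
#'   (a `"warming_scenario"`), `options` (`"solver_options"`) and `run`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  check_keys(raw, c("scenario", "solver", "run"), "config")
  sc_raw <- raw$scenario
  if (is.null(sc_raw)) stop("config.scenario is required")
  if (is.character(sc_raw) && length(sc_raw) == 1)
    sc_raw <- list(preset = sc_raw)
  check_keys(sc_raw, scenario_keys, "scenario")
  mats <- make_material_table()
  if (!is.null(sc_raw$materials)) {
    for (nm in names(sc_raw$materials)) {
      if (!nm %in% names(mats))
        stop("unknown material at scenario.materials.", nm)
      m <- sc_raw$materials[[nm]]
      check_keys(m, c("rho", "cp", "k", "beta", "mu", "phase"),
                 paste0("scenario.materials.", nm))
      base <- unclass(mats[[nm]])
      base[names(m)] <- m
      mats[[nm]] <- do.call(material, c(list(name = nm), base[c(
        "rho", "cp", "k", "beta", "mu", "phase")]))
    }
  }
  sc_args <- sc_raw[setdiff(names(sc_raw), c("preset", "materials"))]
  sc_args$materials <- mats
  scenario <- if (!is.null(sc_raw$preset))
    do.call(bottle_scenario, c(list(preset = sc_raw$preset), sc_args))
  else do.call(cylinder_scenario, sc_args)

  so_raw <- raw$solver
  if (is.null(so_raw)) so_raw <- list()
  check_keys(so_raw, solver_keys, "solver")
  if (!is.null(so_raw$dt) && so_raw$dt <= 0)
    stop("invalid value at solver.dt: must be > 0")
  options <- do.call(solver_options, so_raw)

  rn <- raw$run
  if (is.null(rn)) stop("config.run is required")
  check_keys(rn, run_keys, "run")
  rn$sample_interval <- rn$sample_interval %||% 10
  rn$snapshot_interval <- rn$snapshot_interval %||% 0
  rn$out_dir <- rn$out_dir %||% "milkwarm-out"
  rn$log_level <- rn$log_level %||% "info"
  rn$target_cells <- rn$target_cells %||% 4300
  if (is.null(rn$end_time)) stop("run.end_time is required")
  if (!(rn$sample_interval > 0 && rn$end_time >= rn$sample_interval))
    stop("invalid run section: need end_time >= sample_interval > 0")
  structure(list(scenario = scenario, options = options, run = rn),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run configuration
#'
#' Serializes a `"run_config"` back to YAML, including the full material
#' table at full precision, so that [load_config()] round-trips to an
#' equivalent configuration.
#'
#' @param config a `"run_config"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  sc <- config$scenario
  sc_out <- sc$params
  if (!is.null(sc$preset)) sc_out <- c(list(preset = sc$preset), sc_out)
  sc_out$materials <- lapply(sc$materials, function(m) {
    out <- list(rho = m$rho, cp = m$cp, k = m$k, phase = m$phase)
    if (m$phase != "solid") { out$beta <- m$beta; out$mu <- m$mu }
    out
  })
  so <- unclass(config$options)
  so$t_ref <- NULL
  out <- list(scenario = sc_out, solver = so, run = config$run)
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Write a metrics series to CSV
#'
#' Comma-separated, `.` decimal, UTF-8, LF endings, header
#' `time_s,pat_C,frac_above_40,t_min_C,t_max_C`, 15 significant digits.
#'
#' @param metrics metrics data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  fm <- metrics
  for (cn in names(fm)) fm[[cn]] <- sprintf("%.15g", fm[[cn]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(fm), collapse = ","), con, sep = "\n")
  if (nrow(fm) > 0)
    writeLines(do.call(paste, c(unname(as.list(fm)), sep = ",")), con,
               sep = "\n")
  invisible(path)
}

#' Read a metrics CSV written by [write_metrics_csv()]
#' @param path file path.
#' @return data.frame.
#' @export
read_metrics_csv <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}

#' Write a VTK (legacy ASCII) snapshot
#'
#' Exports the active cells of the mesh as an unstructured grid of
#' quadrilaterals in the (r, z) plane, with cell data `region`, and, when a
#' field state is given, `T`, `p`, the velocity as a 3-vector (zero swirl
#' component) and the node field `psi` (Stokes stream function).
#'
#' @param mesh an `"aximesh"`.
#' @param path output file path.
#' @param state optional `"field_state"`.
#' @return `path`, invisibly.
#' @export
write_vtk_snapshot <- function(mesh, path, state = NULL) {
  nr <- mesh$nr; nz <- mesh$nz
  act <- which(!is.na(mesh$region))
  ii <- (act - 1) %% nr + 1
  jj <- (act - 1) %/% nr + 1
  npt <- (nr + 1) * (nz + 1)
  node_id <- function(i, j) (j - 1) * (nr + 1) + i  # 1-based node index
  con <- file(path, open = "wb")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con, sep = "\n")
  w("# vtk DataFile Version 3.0")
  w("milkwarm axisymmetric snapshot%s",
    if (!is.null(state)) sprintf(" t=%g s", state$time) else "")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS %d double", npt)
  pts <- expand.grid(r = mesh$redge, z = mesh$zedge)
  writeLines(sprintf("%.9g %.9g 0", pts$r, pts$z), con, sep = "\n")
  nc <- length(act)
  w("CELLS %d %d", nc, 5 * nc)
  writeLines(sprintf("4 %d %d %d %d",
                     node_id(ii, jj) - 1L, node_id(ii + 1, jj) - 1L,
                     node_id(ii + 1, jj + 1) - 1L, node_id(ii, jj + 1) - 1L),
             con, sep = "\n")
  w("CELL_TYPES %d", nc)
  writeLines(rep("9", nc), con, sep = "\n")   # VTK_QUAD
  w("CELL_DATA %d", nc)
  w("SCALARS region int 1")
  w("LOOKUP_TABLE default")
  writeLines(sprintf("%d", mesh$region[act]), con, sep = "\n")
  if (!is.null(state)) {
    w("SCALARS T double 1")
    w("LOOKUP_TABLE default")
    writeLines(sprintf("%.9g", state$T[act]), con, sep = "\n")
    w("SCALARS p double 1")
    w("LOOKUP_TABLE default")
    writeLines(sprintf("%.9g", state$p[act]), con, sep = "\n")
    w("VECTORS velocity double")
    writeLines(sprintf("%.9g %.9g 0", state$ur[act], state$uz[act]),
               con, sep = "\n")
    psi <- stream_function(state, mesh)
    w("POINT_DATA %d", npt)
    w("SCALARS psi double 1")
    w("LOOKUP_TABLE default")
    writeLines(sprintf("%.9g", as.numeric(psi)), con, sep = "\n")
  }
  invisible(path)
}

#' Write run outputs to a directory
#'
#' Writes the metrics CSV, one VTK file per stored snapshot and a
#' `manifest.json` listing every file with its MD5 checksum.
#'
#' @param run a `"warming_run"`.
#' @param out_dir output directory (created if needed).
#' @return The manifest as a list, invisibly.
#' @export
write_outputs <- function(run, out_dir) {
  stopifnot(inherits(run, "warming_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  csv <- file.path(out_dir, "metrics.csv")
  write_metrics_csv(run$metrics, csv)
  files <- c(files, csv)
  for (nm in names(run$snapshots)) {
    f <- file.path(out_dir, paste0("snapshot_", sub("^t", "", nm), "s.vtk"))
    write_vtk_snapshot(run$mesh, f, run$snapshots[[nm]])
    files <- c(files, f)
  }
  manifest <- list(files = lapply(files, function(f)
    list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  mf <- file.path(out_dir, "manifest.json")
  writeLines(to_json(manifest), mf)
  mw_log("info", "wrote ", length(files), " file(s) + manifest to ", out_dir)
  invisible(manifest)
}

# minimal JSON emitter (strings, numbers, lists)
to_json <- function(x, indent = 0) {
  pad <- strrep(" ", indent)
  if (is.list(x)) {
    if (is.null(names(x))) {
      items <- vapply(x, to_json, "", indent = indent + 2)
      paste0("[\n", paste0(pad, "  ", items, collapse = ",\n"), "\n", pad, "]")
    } else {
      items <- vapply(seq_along(x), function(k)
        paste0("\"", names(x)[k], "\": ", to_json(x[[k]], indent + 2)), "")
      paste0("{\n", paste0(pad, "  ", items, collapse = ",\n"), "\n", pad, "}")
    }
  } else if (is.character(x)) paste0("\"", x, "\"")
  else sprintf("%.15g", x)
}

#' Execute a run configuration
#'
#' Runs the simulation described by a `"run_config"` and writes its
#' outputs.
#'
#' @param config a `"run_config"` from [load_config()].
#' @return The `"warming_run"`, invisibly.
#' @export
run_from_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  old <- options(milkwarm.log_level = config$run$log_level)
  on.exit(options(old))
  rn <- config$run
  snaps <- if (rn$snapshot_interval > 0)
    seq(rn$snapshot_interval, rn$end_time, by = rn$snapshot_interval)
  else numeric(0)
  mw_log("info", "simulating to t=", rn$end_time, " s (dt=",
         config$options$dt, " s, ~", rn$target_cells, " cells)")
  run <- simulate_warming(config$scenario, config$options,
                          end_time = rn$end_time,
                          sample_interval = rn$sample_interval,
                          target_cells = rn$target_cells,
                          snapshot_times = snaps)
  write_outputs(run, rn$out_dir)
  invisible(run)
}
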