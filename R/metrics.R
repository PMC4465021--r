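# Summaries of simulated fields: mass-weighted mean temperature, volume
# fractions by temperature band, extrema, threshold-crossing times and the
# Stokes stream function.

region_cells <- function(mesh, region) {
  k <- match(region, mesh$region_names)
  if (is.na(k)) stop("unknown region '", region, "'; regions: ",
                     paste(mesh$region_names, collapse = ", "))
  idx <- which(mesh$region == k)
  if (length(idx) == 0) stop("region '", region, "' has no cells")
  idx
}

#' Mass-weighted mean temperature over a region
#'
#' Since density is constant within a region this is the volume-weighted
#' mean: `sum(rho*V*T) / sum(rho*V)`.
#'
#' @param state a `"field_state"`.
#' @param mesh an `"aximesh"`.
#' @param region region name (default `"milk"`).
#' @return Temperature in degrees C.
#' @export
mass_weighted_mean_temperature <- function(state, mesh, region = "milk") {
  idx <- region_cells(mesh, region)
  v <- cell_volumes(mesh)[idx]
  sum(v * state$T[idx]) / sum(v)
}

#' Volume fraction of a region within a temperature band
#'
#' Uses half-open membership `T_lo <= T < T_hi` so that fractions over a
#' partition of bands always add to one.
#'
#' @param state a `"field_state"`.
#' @param mesh an `"aximesh"`.
#' @param region region name.
#' @param t_lo,t_hi band limits in degrees C (`t_hi` may be `Inf`).
#' @return Fraction in \[0, 1\].
#' @export
fraction_in_range <- function(state, mesh, region = "milk", t_lo, t_hi = Inf) {
  if (!(t_lo < t_hi)) stop("t_lo must be < t_hi")
  idx <- region_cells(mesh, region)
  v <- cell_volumes(mesh)[idx]
  Tr <- state$T[idx]
  sum(v[Tr >= t_lo & Tr < t_hi]) / sum(v)
}

#' Temperature extrema over a region
#'
#' @inheritParams mass_weighted_mean_temperature
#' @return Named numeric vector `c(t_min =, t_max =)` in degrees C.
#' @export
region_extrema <- function(state, mesh, region = "milk") {
  idx <- region_cells(mesh, region)
  Tr <- state$T[idx]
  c(t_min = min(Tr), t_max = max(Tr))
}

#' One metrics record
#'
#' @inheritParams mass_weighted_mean_temperature
#' @return One-row data.frame with `time_s`, `pat_C`, `frac_above_40`,
#'   `t_min_C`, `t_max_C`.
#' @export
metrics_record <- function(state, mesh, region = "milk") {
  ex <- region_extrema(state, mesh, region)
  data.frame(time_s = state$time,
             pat_C = mass_weighted_mean_temperature(state, mesh, region),
             frac_above_40 = fraction_in_range(state, mesh, region, 40, Inf),
             t_min_C = unname(ex["t_min"]),
             t_max_C = unname(ex["t_max"]))
}

#' First crossing time of a metric threshold
#'
#' Linearly interpolates the first upward crossing of `threshold` by the
#' chosen statistic of a metrics series.
#'
#' @param series metrics data.frame as produced by [simulate_warming()].
#' @param threshold temperature threshold in degrees C.
#' @param statistic `"pat"` (mass-weighted mean) or `"t_max"`.
#' @return Crossing time in seconds, `0` if the series starts above the
#'   threshold, or `NA` if the threshold is never reached.
#' @export
time_to_threshold <- function(series, threshold, statistic = c("pat", "t_max")) {
  statistic <- match.arg(statistic)
  if (nrow(series) == 0) stop("empty metrics series")
  y <- series[[if (statistic == "pat") "pat_C" else "t_max_C"]]
  t <- series$time_s
  if (y[1] >= threshold) return(0)
  above <- which(y >= threshold)
  if (length(above) == 0) return(NA_real_)
  k <- above[1]
  t[k - 1] + (threshold - y[k - 1]) / (y[k] - y[k - 1]) * (t[k] - t[k - 1])
}

#' Stokes stream function on mesh nodes
#'
#' Integrates `psi(r, z) = integral of r*u_z dr` outward from the axis
#' (where `psi = 0`), so that `u_z = (1/r) dpsi/dr` and
#' `u_r = -(1/r) dpsi/dz`.  Solid cells carry zero velocity and therefore
#' contribute nothing; contours of `psi` are streamlines of the
#' axisymmetric flow.
#'
#' @param state a `"field_state"`.
#' @param mesh an `"aximesh"`.
#' @return Matrix of `psi` values at mesh nodes, `(nr+1) x (nz+1)`, in
#'   m^3/s (per radian).
#' @export
stream_function <- function(state, mesh) {
  nr <- mesh$nr; nz <- mesh$nz
  uz <- state$uz
  # u_z on node rows: average the two cell layers meeting at each z edge
  uzn <- matrix(0, nr, nz + 1)
  uzn[, 1] <- uz[, 1]
  uzn[, nz + 1] <- uz[, nz]
  if (nz > 1) uzn[, 2:nz] <- (uz[, 1:(nz - 1)] + uz[, 2:nz]) / 2
  r2 <- mesh$redge^2
  psi <- matrix(0, nr + 1, nz + 1)
  for (i in seq_len(nr))
    psi[i + 1, ] <- psi[i, ] + uzn[i, ] * (r2[i + 1] - r2[i]) / 2
  psi
}
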