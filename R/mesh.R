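# Structured axisymmetric quadrilateral meshing.
#
# The mesh is a tensor-product grid in (r, z) whose grid lines are snapped
# to every material interface, so no cell ever spans two materials and all
# conjugate interfaces coincide with cell faces.  Cells outside all regions
# (the air above the bath water line, outside the bottle) are inactive.

#' Build the axisymmetric mesh for a scenario
#'
#' Subdivides the scenario's (r, z) bounding box into a structured grid of
#' quadrilateral cells with grid lines snapped to all region interfaces.
#' Spacing is near-uniform; the number of active cells comes out within
#' 15 % of `target_cells`.
#'
#' @param scenario a `"warming_scenario"`.
#' @param target_cells requested number of active cells (>= 100).
#' @return An object of class `"aximesh"`: `redge`/`zedge` (cell edge
#'   coordinates, metres), `region` (integer matrix of region ids, `NA` for
#'   inactive cells), `region_names`, `materials`, and the originating
#'   `scenario`.
#' @examples
#' m <- build_mesh(bottle_scenario("bottle1"), target_cells = 1000)
#' region_volume(m, "milk") * 1e6   # close to 60 ml
#' @export
build_mesh <- function(scenario, target_cells = 4300) {
  stopifnot(inherits(scenario, "warming_scenario"))
  if (target_cells < 100) stop("target_cells must be >= 100")
  rects <- lapply(scenario$regions, `[[`, "extent")
  names(rects) <- vapply(scenario$regions, `[[`, "", "name")
  allr <- do.call(rbind, rects)
  rbreaks <- sort(unique(signif(c(allr$r0, allr$r1), 12)))
  zbreaks <- sort(unique(signif(c(allr$z0, allr$z1), 12)))
  rint <- diff(rbreaks); zint <- diff(zbreaks)
  if (any(rint < 1e-5) || any(zint < 1e-5)) {
    thin <- which.min(c(rint, zint))
    stop("geometry too thin to resolve: interval of ",
         signif(min(c(rint, zint)) * 1000, 3), " mm near region '",
         thin_region_name(scenario, rbreaks, zbreaks), "'")
  }

  Rtot <- max(rbreaks) - min(rbreaks)
  Ztot <- max(zbreaks) - min(zbreaks)
  h <- sqrt(Rtot * Ztot / target_cells)
  mk_edges <- function(breaks, h) {
    out <- breaks[1]
    for (k in seq_along(breaks)[-1]) {
      len <- breaks[k] - breaks[k - 1]
      n <- max(1L, round(len / h))
      out <- c(out, breaks[k - 1] + len * seq_len(n) / n)
    }
    out
  }
  best <- NULL
  for (iter in 1:40) {
    redge <- mk_edges(rbreaks, h)
    zedge <- mk_edges(zbreaks, h)
    region <- assign_regions(redge, zedge, rects)
    nact <- sum(!is.na(region))
    if (is.null(best) || abs(nact - target_cells) < abs(best$nact - target_cells))
      best <- list(redge = redge, zedge = zedge, region = region, nact = nact)
    if (abs(nact - target_cells) / target_cells <= 0.05) break
    h <- h * sqrt(nact / target_cells)
  }
  if (abs(best$nact - target_cells) / target_cells > 0.15)
    stop("could not mesh within 15% of target_cells (got ", best$nact, ")")

  structure(list(
    redge = best$redge, zedge = best$zedge,
    nr = length(best$redge) - 1L, nz = length(best$zedge) - 1L,
    region = best$region,
    region_names = names(rects),
    materials = lapply(scenario$regions, `[[`, "material"),
    n_active = best$nact,
    scenario = scenario
  ), class = "aximesh")
}

thin_region_name <- function(scenario, rbreaks, zbreaks) {
  rint <- diff(rbreaks); zint <- diff(zbreaks)
  if (min(rint) < min(zint)) {
    k <- which.min(rint); mid <- (rbreaks[k] + rbreaks[k + 1]) / 2
    for (rg in scenario$regions)
      if (any(rg$extent$r0 <= mid & mid <= rg$extent$r1)) return(rg$name)
  } else {
    k <- which.min(zint); mid <- (zbreaks[k] + zbreaks[k + 1]) / 2
    for (rg in scenario$regions)
      if (any(rg$extent$z0 <= mid & mid <= rg$extent$z1)) return(rg$name)
  }
  "unknown"
}

assign_regions <- function(redge, zedge, rects) {
  nr <- length(redge) - 1L; nz <- length(zedge) - 1L
  rc <- (redge[-1] + redge[-length(redge)]) / 2
  zc <- (zedge[-1] + zedge[-length(zedge)]) / 2
  region <- matrix(NA_integer_, nr, nz)
  for (k in seq_along(rects)) {
    ex <- rects[[k]]
    for (q in seq_len(nrow(ex))) {
      ri <- which(rc > ex$r0[q] & rc < ex$r1[q])
      zi <- which(zc > ex$z0[q] & zc < ex$z1[q])
      region[ri, zi] <- k
    }
  }
  region
}

#' Cell volumes of an axisymmetric mesh
#' @param mesh an `"aximesh"`.
#' @return Matrix (nr x nz) of cell volumes `2*pi*r_c*dr*dz` in m^3.
#' @export
cell_volumes <- function(mesh) {
  dr <- diff(mesh$redge)
  rc <- (mesh$redge[-1] + mesh$redge[-length(mesh$redge)]) / 2
  dz <- diff(mesh$zedge)
  outer(2 * pi * rc * dr, dz)
}

#' Total meshed volume of a region
#' @param mesh an `"aximesh"`.
#' @param region region name.
#' @return Volume in m^3.
#' @export
region_volume <- function(mesh, region) {
  k <- match(region, mesh$region_names)
  if (is.na(k)) stop("unknown region '", region, "'; regions: ",
                     paste(mesh$region_names, collapse = ", "))
  v <- cell_volumes(mesh)
  sum(v[which(mesh$region == k)])
}

#' Exterior boundary faces of the mesh
#'
#' Enumerates every exterior face (a face between an active cell and either
#' the domain edge or an inactive cell) together with the boundary tag it
#' maps to.
#'
#' @param mesh an `"aximesh"`.
#' @return data.frame with columns `i`, `j` (cell indices), `side` (one of
#'   `"W","E","S","N"`), `tag` and `area` (m^2).
#' @export
boundary_faces <- function(mesh) {
  nr <- mesh$nr; nz <- mesh$nz
  reg <- mesh$region
  bath_id <- match("bath_water", mesh$region_names)
  rows <- list()
  areaE <- outer(2 * pi * mesh$redge[-1], diff(mesh$zedge))
  areaW <- outer(2 * pi * mesh$redge[-(nr + 1)], diff(mesh$zedge))
  dr <- diff(mesh$redge)
  rc <- (mesh$redge[-1] + mesh$redge[-(nr + 1)]) / 2
  areaNS <- matrix(2 * pi * rc * dr, nr, nz)
  for (j in seq_len(nz)) for (i in seq_len(nr)) {
    if (is.na(reg[i, j])) next
    for (side in c("W", "E", "S", "N")) {
      ni <- i + (side == "E") - (side == "W")
      nj <- j + (side == "N") - (side == "S")
      ext <- ni < 1 || ni > nr || nj < 1 || nj > nz || is.na(reg[ni, nj])
      if (!ext) next
      tag <- boundary_tag(mesh, i, j, side, bath_id)
      area <- switch(side, W = areaW[i, j], E = areaE[i, j],
                     S = areaNS[i, j], N = areaNS[i, j])
      rows[[length(rows) + 1L]] <-
        data.frame(i = i, j = j, side = side, tag = tag, area = area)
    }
  }
  do.call(rbind, rows)
}

# Tagging rules for exterior faces of the composite cylinder geometry.
boundary_tag <- function(mesh, i, j, side, bath_id) {
  if (side == "W" && i == 1) return("axis")
  if (side == "S" && j == 1) return("heater_bottom")
  is_bath <- !is.na(mesh$region[i, j]) && mesh$region[i, j] == bath_id
  if (side == "E" && i == mesh$nr && is_bath) return("heater_side")
  if (side == "N" && is_bath) return("bath_surface")
  "ambient"
}

#' @export
print.aximesh <- function(x, ...) {
  cat(sprintf("<aximesh> %d x %d cells (%d active) over %.1f x %.1f mm\n",
              x$nr, x$nz, x$n_active,
              1000 * diff(range(x$redge)), 1000 * diff(range(x$zedge))))
  v <- cell_volumes(x)
  for (k in seq_along(x$region_names))
    cat(sprintf("  %-14s %8.2f ml\n", x$region_names[k],
                1e6 * sum(v[which(x$region == k)])))
  invisible(x)
}
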