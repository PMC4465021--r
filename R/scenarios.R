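# Scenario definitions: geometry, materials, initial and boundary conditions
# for the axisymmetric bottle-in-water-bath system.
#
# The modelled geometry is a set of coaxial cylinders: the bottle interior
# (milk below, headspace air above, closed by a plastic nipple cap), the
# plastic bottle wall and bottom, and an annular gap of bath water around
# the bottle.  The heater holds the bath's outer and bottom boundaries (and
# the underside of the bottle) at the bath temperature; everything above
# the bath water line loses heat to ambient air by Newton cooling.

#' Build a cylindrical bottle-warming scenario
#'
#' Constructs the full problem definition (regions, materials, initial and
#' boundary conditions) for a bottle of given milk volume, nominal total
#' volume and height standing in an annular hot-water bath.  The inner
#' bottle radius is solved from the nominal total volume and height as a
#' plain cylinder, `R = sqrt(V / (pi * H))`, so the printed volumes, which
#' control the thermal mass, are preserved exactly.
#'
#' @param milk_volume_ml milk volume in millilitres.
#' @param total_volume_ml nominal total bottle volume in millilitres.
#' @param height_mm bottle height (including nipple) in millimetres.
#' @param wall_mm bottle wall thickness in millimetres.
#' @param gap_mm radial width of the annular bath-water gap in millimetres.
#' @param bath_above_milk_mm bath water level above the milk level, mm.
#' @param cap_mm thickness of the plastic nipple cap closing the top, mm.
#' @param bath_temperature heater/bath temperature in degrees C.
#' @param initial_temperature initial temperature of bottle, nipple, milk
#'   and headspace air in degrees C.
#' @param ambient_temperature ambient air temperature for Newton cooling,
#'   degrees C.
#' @param h_ambient ambient heat-transfer coefficient in W/(m^2 K).
#' @param gravity gravitational acceleration magnitude in m/s^2, directed
#'   along -z.
#' @param materials named material table, see [make_material_table()].
#'
#' @return An object of class `"warming_scenario"` with elements `regions`
#'   (list of region specs with axisymmetric rectangle extents in metres),
#'   `boundaries`, `initial_temperatures`, `milk_volume` (ml),
#'   `total_bottle_volume` (ml), `bottle_height` (mm), `gravity`, `params`
#'   (the constructor arguments) and `dims` (derived geometry in metres).
#' @seealso [bottle_scenario()], [random_scenario()]
#' @export
cylinder_scenario <- function(milk_volume_ml, total_volume_ml, height_mm,
                              wall_mm = 2, gap_mm = 5, bath_above_milk_mm = 10,
                              cap_mm = 4, bath_temperature = 80,
                              initial_temperature = 4,
                              ambient_temperature = 18, h_ambient = 10.45,
                              gravity = 9.81,
                              materials = make_material_table()) {
  stopifnot(milk_volume_ml > 0, total_volume_ml > milk_volume_ml,
            height_mm > 0, wall_mm > 0, gap_mm > 0, cap_mm > 0)
  if (bath_temperature < 0 || bath_temperature > 100 ||
      initial_temperature < 0 || initial_temperature > 100)
    stop("initial temperatures must lie within [0, 100] C")

  H <- height_mm / 1000
  tw <- wall_mm / 1000
  gap <- gap_mm / 1000
  cap <- cap_mm / 1000
  Vmilk <- milk_volume_ml * 1e-6
  Vtot <- total_volume_ml * 1e-6

  R_in <- sqrt(Vtot / (pi * H))
  R_wall <- R_in + tw
  R_out <- R_wall + gap
  h_milk <- Vmilk / (pi * R_in^2)
  z_milk_top <- tw + h_milk
  z_cap_bottom <- H - cap
  if (z_milk_top >= z_cap_bottom)
    stop("milk level reaches the nipple cap; no headspace remains ",
         "(milk ", milk_volume_ml, " ml is too large for this bottle)")
  z_bath <- min(z_milk_top + bath_above_milk_mm / 1000, H)

  rect <- function(r0, r1, z0, z1) data.frame(r0 = r0, r1 = r1, z0 = z0, z1 = z1)
  regions <- list(
    list(name = "bottle_wall", material = materials$plastic,
         extent = rbind(rect(0, R_wall, 0, tw),
                        rect(R_in, R_wall, tw, H))),
    list(name = "milk", material = materials$milk,
         extent = rect(0, R_in, tw, z_milk_top)),
    list(name = "headspace_air", material = materials$air,
         extent = rect(0, R_in, z_milk_top, z_cap_bottom)),
    list(name = "nipple", material = materials$plastic,
         extent = rect(0, R_in, z_cap_bottom, H)),
    list(name = "bath_water", material = materials$water,
         extent = rect(R_wall, R_out, 0, z_bath))
  )
  boundaries <- list(
    list(tag = "axis", kind = "symmetry_axis"),
    list(tag = "heater_bottom", kind = "fixed_temperature",
         T_wall = bath_temperature),
    list(tag = "heater_side", kind = "fixed_temperature",
         T_wall = bath_temperature),
    list(tag = "bath_surface", kind = "shear_free_interface",
         h = h_ambient, T_ambient = ambient_temperature),
    list(tag = "ambient", kind = "convective",
         h = h_ambient, T_ambient = ambient_temperature)
  )
  sc <- structure(list(
    regions = regions,
    boundaries = boundaries,
    initial_temperatures = c(bottle_wall = initial_temperature,
                             milk = initial_temperature,
                             headspace_air = initial_temperature,
                             nipple = initial_temperature,
                             bath_water = bath_temperature),
    milk_volume = milk_volume_ml,
    total_bottle_volume = total_volume_ml,
    bottle_height = height_mm,
    gravity = gravity,
    params = list(milk_volume_ml = milk_volume_ml,
                  total_volume_ml = total_volume_ml, height_mm = height_mm,
                  wall_mm = wall_mm, gap_mm = gap_mm,
                  bath_above_milk_mm = bath_above_milk_mm, cap_mm = cap_mm,
                  bath_temperature = bath_temperature,
                  initial_temperature = initial_temperature,
                  ambient_temperature = ambient_temperature,
                  h_ambient = h_ambient, gravity = gravity),
    materials = materials,
    dims = list(R_in = R_in, R_wall = R_wall, R_out = R_out, H = H,
                t_wall = tw, cap = cap, h_milk = h_milk,
                z_milk_top = z_milk_top, z_cap_bottom = z_cap_bottom,
                z_bath = z_bath)
  ), class = "warming_scenario")
  validate_scenario(sc)
  sc
}

#' Paper bottle presets
#'
#' Two standard upright-bottle presets: a small bottle holding 60 ml of
#' milk (49 mm tall, 107 ml nominal volume) and a large bottle holding
#' 178 ml (140 mm tall, 324 ml nominal volume), both initially refrigerated
#' at 4 C and immersed in an 80 C water bath.
#'
#' @param preset `"bottle1"` (small) or `"bottle2"` (large).
#' @param ... overrides passed on to [cylinder_scenario()].
#' @return A `"warming_scenario"` object.
#' @examples
#' sc <- bottle_scenario("bottle1")
#' sc$milk_volume    # 60
#' @export
bottle_scenario <- function(preset, ...) {
  presets <- list(
    bottle1 = list(milk_volume_ml = 60, total_volume_ml = 107, height_mm = 49),
    bottle2 = list(milk_volume_ml = 178, total_volume_ml = 324, height_mm = 140)
  )
  if (length(preset) != 1 || !preset %in% names(presets))
    stop("unknown preset '", paste(preset, collapse = ","),
         "'; valid presets: ", paste(names(presets), collapse = ", "))
  args <- utils::modifyList(presets[[preset]], list(...))
  sc <- do.call(cylinder_scenario, args)
  sc$preset <- preset
  sc
}

#' List available scenario presets
#' @return Character vector of preset names.
#' @export
scenario_presets <- function() c("bottle1", "bottle2")

#' Randomized scenario generator
#'
#' Draws a random but physically valid bottle-warming scenario: milk volume
#' 30-250 ml, bath temperature 40-90 C, initial contents temperature
#' 2-25 C, wall thickness 1-3 mm, with bottle radius and headspace sampled
#' so that all geometric invariants hold.  Deterministic in `seed`; the
#' caller's RNG state is left untouched.
#'
#' @param seed integer seed.
#' @return A `"warming_scenario"` object.
#' @export
random_scenario <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  milk <- stats::runif(1, 30, 250)
  total <- milk * stats::runif(1, 1.5, 2.5)
  # radius chosen so that at least 8 mm of headspace air remains below the cap
  R_max <- sqrt((total - milk) * 1e-6 / (pi * 0.012))
  R <- stats::runif(1, 0.018, max(0.0181, min(0.032, R_max)))
  H <- total * 1e-6 / (pi * R^2)
  cylinder_scenario(
    milk_volume_ml = milk,
    total_volume_ml = total,
    height_mm = H * 1000,
    wall_mm = stats::runif(1, 1, 3),
    bath_temperature = stats::runif(1, 40, 90),
    initial_temperature = stats::runif(1, 2, 25)
  )
}

# Axisymmetric volume of a rectangle union (m^3)
extent_volume <- function(extent) {
  sum(pi * (extent$r1^2 - extent$r0^2) * (extent$z1 - extent$z0))
}

#' Validate a scenario
#'
#' Checks the scenario invariants: positive material properties, pairwise
#' non-overlapping regions, milk extent integrating to the declared milk
#' volume within 1 %, initial temperatures within \[0, 100\] C, and exactly
#' one symmetry-axis boundary.
#'
#' @param scenario a `"warming_scenario"` object.
#' @return The scenario, invisibly; errors on violation.
#' @export
validate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "warming_scenario"))
  rects <- do.call(rbind, lapply(scenario$regions, function(rg) {
    cbind(rg$extent, name = rg$name)
  }))
  n <- nrow(rects)
  for (a in seq_len(n - 1)) for (b in seq(a + 1, n)) {
    ovr <- min(rects$r1[a], rects$r1[b]) - max(rects$r0[a], rects$r0[b])
    ovz <- min(rects$z1[a], rects$z1[b]) - max(rects$z0[a], rects$z0[b])
    if (ovr > 1e-12 && ovz > 1e-12)
      stop("regions overlap: ", rects$name[a], " and ", rects$name[b])
  }
  milk <- scenario$regions[[which(vapply(scenario$regions, `[[`, "", "name") == "milk")]]
  vm <- extent_volume(milk$extent)
  if (abs(vm - scenario$milk_volume * 1e-6) > 0.01 * scenario$milk_volume * 1e-6)
    stop("milk extent volume ", vm * 1e6, " ml deviates from declared ",
         scenario$milk_volume, " ml by more than 1%")
  if (any(scenario$initial_temperatures < 0 | scenario$initial_temperatures > 100))
    stop("initial temperatures must lie within [0, 100] C")
  kinds <- vapply(scenario$boundaries, `[[`, "", "kind")
  if (sum(kinds == "symmetry_axis") != 1)
    stop("exactly one symmetry_axis boundary is required")
  invisible(scenario)
}

#' @export
print.warming_scenario <- function(x, ...) {
  cat("<warming_scenario>",
      if (!is.null(x$preset)) paste0(" preset=", x$preset), "\n", sep = "")
  cat(sprintf("  milk %.5g ml, bottle %.5g ml nominal, height %.5g mm\n",
              x$milk_volume, x$total_bottle_volume, x$bottle_height))
  cat(sprintf("  inner radius %.2f mm, wall %.2g mm, bath gap %.2g mm\n",
              x$dims$R_in * 1000, x$dims$t_wall * 1000,
              (x$dims$R_out - x$dims$R_wall) * 1000))
  cat(sprintf("  bath %.4g C, contents %.4g C, ambient %.4g C\n",
              x$params$bath_temperature, x$params$initial_temperature,
              x$params$ambient_temperature))
  invisible(x)
}
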