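#' Thermophysical material description
#'
#' Bundles the constant thermophysical properties of one substance.  Solids
#' carry only density, specific heat and conductivity; fluids additionally
#' need a dynamic viscosity and a thermal expansion coefficient for the
#' Boussinesq buoyancy term.
#'
#' @param name label for the material.
#' @param rho density in kg/m^3.
#' @param cp specific heat capacity in J/(kg K).
#' @param k thermal conductivity in W/(m K).
#' @param beta thermal expansion coefficient in 1/K (fluids only).
#' @param mu dynamic viscosity in Pa s (fluids only).
#' @param phase one of `"solid"`, `"liquid"`, `"gas"`.
#'
#' @return An object of class `"milk_material"`.
#' @examples
#' material("water", rho = 998.2, cp = 4182, k = 0.6,
#'          beta = 2.07e-4, mu = 1e-3, phase = "liquid")
#' @export
material <- function(name, rho, cp, k, beta = NA_real_, mu = NA_real_,
                     phase = c("solid", "liquid", "gas")) {
  phase <- match.arg(phase)
  stopifnot(is.character(name), length(name) == 1)
  if (!(is.numeric(rho) && rho > 0)) stop("material '", name, "': rho must be > 0")
  if (!(is.numeric(cp) && cp > 0)) stop("material '", name, "': cp must be > 0")
  if (!(is.numeric(k) && k > 0)) stop("material '", name, "': k must be > 0")
  if (phase == "solid") {
    if (!is.na(beta) || !is.na(mu))
      stop("material '", name, "': solids must not carry beta or mu")
  } else {
    if (!(is.numeric(mu) && !is.na(mu) && mu > 0))
      stop("material '", name, "': fluids require mu > 0")
    if (!(is.numeric(beta) && !is.na(beta) && beta >= 0))
      stop("material '", name, "': fluids require beta >= 0")
  }
  structure(list(name = name, rho = as.numeric(rho), cp = as.numeric(cp),
                 k = as.numeric(k), beta = as.numeric(beta),
                 mu = as.numeric(mu), phase = phase),
            class = "milk_material")
}

#' @export
print.milk_material <- function(x, ...) {
  cat(sprintf("<material %s (%s)> rho=%g kg/m^3, cp=%g J/(kg K), k=%g W/(m K)",
              x$name, x$phase, x$rho, x$cp, x$k))
  if (x$phase != "solid")
    cat(sprintf(", beta=%g 1/K, mu=%g Pa s", x$beta, x$mu))
  cat("\n")
  invisible(x)
}

#' Reference material table
#'
#' Properties of the four substances in the bottle/bath system: a generic
#' plastic used for both the bottle and the nipple, whole milk, water and
#' air (ideal gas near 18 C).
#'
#' @return Named list of [material()] objects with entries `plastic`,
#'   `milk`, `water` and `air`.
#' @examples
#' tab <- make_material_table()
#' tab$milk$cp   # 3930 J/(kg K)
#' @export
make_material_table <- function() {
  list(
    plastic = material("plastic", rho = 900, cp = 1800, k = 0.2,
                       phase = "solid"),
    milk = material("milk", rho = 1030, cp = 3930, k = 0.5369,
                    beta = 8e-4, mu = 3e-3, phase = "liquid"),
    water = material("water", rho = 998.2, cp = 4182, k = 0.6,
                     beta = 2.07e-4, mu = 1e-3, phase = "liquid"),
    air = material("air", rho = 1.225, cp = 1006, k = 0.0242,
                   beta = 3.43e-3, mu = 1.789e-5, phase = "gas")
  )
}

#' Thermal diffusivity of a material
#'
#' @param material a [material()] object.
#' @return Thermal diffusivity `alpha = k / (rho * cp)` in m^2/s.
#' @examples
#' thermal_diffusivity(make_material_table()$milk)  # about 1.33e-7
#' @export
thermal_diffusivity <- function(material) {
  stopifnot(inherits(material, "milk_material"))
  material$k / (material$rho * material$cp)
}
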