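# Tissue property table and plane-wave electromagnetics at 2.45 GHz.

# vacuum constants (SI)
.mu0 <- 4e-7 * pi
.eps0 <- 8.8541878128e-12

#' Dielectric and thermal properties of one tissue class
#'
#' Container for the static biophysical constants of a single material:
#' relative permittivity and electrical conductivity at the operating
#' microwave frequency, plus the thermal constants used by the bioheat
#' solver. Properties are static (no temperature dependence): bone
#' dielectric/thermal temperature coefficients have not been reported, so
#' the model of record holds them fixed over the ablation.
#'
#' @param name Tissue-class label, e.g. `"cancellous bone"`.
#' @param relative_permittivity Dimensionless relative permittivity
#'   (epsilon_r), > 0.
#' @param electrical_conductivity Effective electrical conductivity sigma
#'   in S/m, >= 0.
#' @param thermal_conductivity Thermal conductivity k in W/m/degC, > 0.
#' @param density Mass density rho in kg/m^3, > 0.
#' @param specific_heat Specific heat capacity c in J/kg/degC, > 0.
#' @return An object of class `tissue_properties` (a named list of the
#'   five constants plus the label).
#' @export
tissue_properties <- function(name, relative_permittivity, electrical_conductivity,
                              thermal_conductivity, density, specific_heat) {
  vals <- c(relative_permittivity = relative_permittivity,
            electrical_conductivity = electrical_conductivity,
            thermal_conductivity = thermal_conductivity,
            density = density, specific_heat = specific_heat)
  stopifnot(is.character(name), length(name) == 1L, all(is.finite(vals)))
  if (electrical_conductivity < 0)
    stop("electrical_conductivity must be >= 0")
  pos <- vals[setdiff(names(vals), "electrical_conductivity")]
  if (any(pos <= 0))
    stop("all properties except electrical_conductivity must be strictly positive")
  structure(c(list(name = name), as.list(vals)), class = "tissue_properties")
}

#' @export
print.tissue_properties <- function(x, ...) {
  cat(sprintf("<tissue_properties> %s\n", x$name))
  cat(sprintf("  eps_r = %g, sigma = %g S/m, k = %g W/m/C, rho = %g kg/m3, c = %g J/kg/C\n",
              x$relative_permittivity, x$electrical_conductivity,
              x$thermal_conductivity, x$density, x$specific_heat))
  invisible(x)
}

#' Material library: tissue classes available to a phantom
#'
#' @param entries Named list of [tissue_properties()]; names must equal each
#'   entry's `name` field.
#' @param frequency Operating frequency in Hz (default 2.45 GHz, the
#'   applicator's ISM band).
#' @return An object of class `material_library`.
#' @export
material_library <- function(entries, frequency = 2.45e9) {
  stopifnot(is.list(entries), length(entries) > 0, frequency > 0)
  nm <- vapply(entries, function(e) e$name, character(1))
  names(entries) <- nm
  structure(list(entries = entries, frequency = frequency),
            class = "material_library")
}

#' Default material library
#'
#' The five canonical tissue classes used in the vertebral-body model
#' (cortical bone, cancellous bone, cartilage, muscle, spinal cord) with
#' their published 2.45 GHz dielectric and thermal constants, plus an
#' `"air"` entry (handbook values; air enters the model only through the
#' convective boundary) and an `"applicator"` placeholder whose thermal
#' constants stand in for the metal shaft when computing the face
#' conductance into the fixed-temperature applicator surface.
#'
#' @param frequency Operating frequency in Hz.
#' @return A [material_library()].
#' @export
load_default_library <- function(frequency = 2.45e9) {
  material_library(list(
    tissue_properties("cortical bone",   11.4, 0.39, 0.32, 1908, 1313),
    tissue_properties("cancellous bone", 18.5, 0.81, 0.31, 1178, 2274),
    tissue_properties("cartilage",       38.8, 1.76, 0.49, 1100, 3568),
    tissue_properties("muscle",          52.7, 1.74, 0.49, 1090, 3421),
    tissue_properties("spinal cord",     30.1, 1.09, 0.51, 1075, 3630),
    tissue_properties("air",             1.0,  0.0,  0.026, 1.2,  1005),
    # stainless-steel-like shaft; only k/rho/c matter (Dirichlet surface)
    tissue_properties("applicator",      1.0,  0.0,  16.0, 7900, 500)
  ), frequency = frequency)
}

#' Look up a tissue class in a material library
#'
#' @param library A [material_library()].
#' @param name Tissue-class label.
#' @return The matching [tissue_properties()].
#' @export
lookup <- function(library, name) {
  stopifnot(inherits(library, "material_library"))
  p <- library$entries[[name]]
  if (is.null(p)) stop(sprintf("tissue class '%s' not in material library", name))
  p
}

#' Plane-wave attenuation constant and penetration depth
#'
#' For a lossy dielectric at angular frequency omega = 2*pi*f, the field
#' attenuation constant is
#' `alpha = omega * sqrt((mu0 eps0 eps_r / 2) * (sqrt(1 + (sigma/(omega eps0 eps_r))^2) - 1))`
#' (Np/m) and the penetration depth is `delta = 1/alpha` (the 1/e field
#' amplitude depth; power decays as `exp(-2 alpha r)`). A lossless medium
#' (sigma = 0) returns alpha = 0 and infinite depth.
#'
#' @param props A [tissue_properties()].
#' @param frequency Frequency in Hz, > 0.
#' @return List with `attenuation_constant` (Np/m) and `penetration_depth` (m).
#' @export
plane_wave_attenuation <- function(props, frequency) {
  stopifnot(inherits(props, "tissue_properties"), frequency > 0)
  w <- 2 * pi * frequency
  er <- props$relative_permittivity
  sg <- props$electrical_conductivity
  loss_tan <- sg / (w * .eps0 * er)
  alpha <- w * sqrt((.mu0 * .eps0 * er / 2) * (sqrt(1 + loss_tan^2) - 1))
  list(attenuation_constant = alpha,
       penetration_depth = if (alpha > 0) 1 / alpha else Inf)
}

#' Write a material library to a YAML config file
#'
#' One block per tissue; numeric values are serialized with 17 significant
#' digits so that a read/write round trip reproduces every double exactly.
#'
#' @param library A [material_library()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_material_library <- function(library, path) {
  stopifnot(inherits(library, "material_library"))
  x <- list(frequency = library$frequency,
            tissues = lapply(unname(library$entries), function(e) {
              e <- unclass(e); e
            }))
  writeLines(yaml::as.yaml(x, precision = 17L), path)
  invisible(path)
}

#' Read a material library from a YAML config file
#'
#' @param path File written by [write_material_library()].
#' @return A [material_library()].
#' @export
read_material_library <- function(path) {
  x <- yaml::read_yaml(path)
  entries <- lapply(x$tissues, function(e) do.call(tissue_properties, e))
  material_library(entries, frequency = x$frequency)
}
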