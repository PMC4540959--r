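# Package-level cache for element attenuation tables and the built-in
# material registry (filled lazily from inst/extdata).
.decbct_env <- new.env(parent = emptyenv())

.element_constants <- data.frame(
  symbol = c("H", "C", "N", "O", "Al", "Si"),
  Z = c(1L, 6L, 7L, 8L, 13L, 14L),
  A = c(1.008, 12.011, 14.007, 15.999, 26.9815385, 28.085),
  stringsAsFactors = FALSE
)

#' Element mass-attenuation table
#'
#' Loads the packaged mass-attenuation coefficient table for one element.
#' Tables cover 10--150 keV on a log-spaced grid; values between grid points
#' are obtained by log-log linear interpolation (the standard scheme for
#' smooth, K-edge-free attenuation data in this range).
#'
#' @param symbol Element symbol; one of "H", "C", "N", "O", "Al", "Si".
#' @return An object of class `element_table` with fields `symbol`, `Z`,
#'   `A` (g/mol), `energies` (keV, ascending) and `mu_over_rho` (cm^2/g).
#' @export
element_table <- function(symbol) {
  key <- paste0("eltab_", symbol)
  if (!is.null(.decbct_env[[key]])) return(.decbct_env[[key]])
  row <- .element_constants[.element_constants$symbol == symbol, ]
  if (nrow(row) != 1L) {
    stop("unknown element: ", symbol, call. = FALSE)
  }
  path <- system.file("extdata", "attenuation", paste0(symbol, ".csv"),
                      package = "decbct", mustWork = TRUE)
  tab <- utils::read.csv(path)
  stopifnot(all(diff(tab$energy_keV) > 0), all(tab$mu_over_rho_cm2_g > 0))
  out <- structure(
    list(symbol = symbol, Z = row$Z, A = row$A,
         energies = tab$energy_keV, mu_over_rho = tab$mu_over_rho_cm2_g),
    class = "element_table")
  .decbct_env[[key]] <- out
  out
}

# log-log interpolation of an element table at arbitrary energies (keV)
.interp_mu_rho <- function(tab, energy) {
  rng <- range(tab$energies)
  if (any(energy < rng[1] - 1e-9) || any(energy > rng[2] + 1e-9)) {
    stop("energy outside supported attenuation range [", rng[1], ", ",
         rng[2], "] keV", call. = FALSE)
  }
  energy <- pmin(pmax(energy, rng[1]), rng[2])
  exp(stats::approx(log(tab$energies), log(tab$mu_over_rho),
                    xout = log(energy))$y)
}

#' Define a material
#'
#' A material is an elemental composition (mass fractions) plus a mass
#' density. Mass fractions must sum to 1 within 1e-6; density must be
#' positive (0 is allowed only as the vacuum sentinel).
#'
#' @param name Label used in reports.
#' @param composition Named numeric vector of elemental mass fractions.
#' @param density Mass density in g/cm^3.
#' @return An object of class `material`.
#' @examples
#' graphite <- material("graphite", c(C = 1), 1.700)
#' electron_density(graphite)
#' @export
material <- function(name, composition, density) {
  composition <- unlist(composition)
  if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
    stop("composition must be a named vector of mass fractions", call. = FALSE)
  }
  unknown <- setdiff(names(composition), .element_constants$symbol)
  if (length(unknown)) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (abs(sum(composition) - 1) > 1e-6) {
    stop("mass fractions must sum to 1 (got ", sum(composition), ")",
         call. = FALSE)
  }
  if (density < 0) stop("density must be >= 0", call. = FALSE)
  structure(list(name = name, composition = composition,
                 density = density),
            class = "material")
}

#' @export
print.material <- function(x, ...) {
  cat(sprintf("<material> %s  rho = %.4g g/cm^3\n", x$name, x$density))
  comp <- paste(sprintf("%s %.5f", names(x$composition), x$composition),
                collapse = ", ")
  cat("  composition:", comp, "\n")
  invisible(x)
}

#' Built-in material registry
#'
#' Returns one of the materials defined in the packaged registry
#' (`inst/extdata/materials.yaml`): water, graphite, aluminum, silicon,
#' pmma, pe, vacuum. The density can be overridden, e.g. to match a
#' vendor-stated insert density.
#'
#' @param name Registry key (case-insensitive).
#' @param density Optional density override in g/cm^3.
#' @return A `material`.
#' @export
get_material <- function(name, density = NULL) {
  reg <- .material_registry()
  key <- tolower(name)
  if (is.null(reg[[key]])) {
    stop("unknown material '", name, "'; registered: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  m <- reg[[key]]
  if (!is.null(density)) m <- material(m$name, m$composition, density)
  m
}

.material_registry <- function() {
  if (!is.null(.decbct_env$registry)) return(.decbct_env$registry)
  path <- system.file("extdata", "materials.yaml", package = "decbct",
                      mustWork = TRUE)
  .decbct_env$registry <- .parse_material_yaml(path)
  .decbct_env$registry
}

#' Register materials from a YAML file
#'
#' Reads a YAML file with entries `name: {density: ..., composition: {El:
#' fraction, ...}}` and returns a named list of `material` objects. Used for
#' the built-in registry and for user-supplied custom materials.
#'
#' @param path Path to the YAML file.
#' @return Named list of `material` objects.
#' @export
read_materials_yaml <- function(path) .parse_material_yaml(path)

.parse_material_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    material(nm, unlist(raw[[nm]]$composition), raw[[nm]]$density)
  })
  names(out) <- tolower(names(raw))
  out
}

#' Mass attenuation coefficient of a material
#'
#' Applies the elemental mixture rule sum_i w_i (mu/rho)_i(E) with log-log
#' interpolation of the packaged element tables.
#'
#' @param mat A `material`.
#' @param energy Photon energy in keV (vectorised); must lie in 10--150 keV.
#' @return Mass attenuation coefficient(s) in cm^2/g.
#' @export
mass_attenuation <- function(mat, energy) {
  stopifnot(inherits(mat, "material"))
  out <- numeric(length(energy))
  for (el in names(mat$composition)) {
    out <- out + mat$composition[[el]] * .interp_mu_rho(element_table(el),
                                                       energy)
  }
  out
}

#' Linear attenuation coefficient of a material
#'
#' mu = (mu/rho) * rho, converted from 1/cm to 1/mm (all geometric lengths
#' in the package are millimetres).
#'
#' @inheritParams mass_attenuation
#' @return Linear attenuation coefficient(s) in 1/mm.
#' @export
linear_attenuation <- function(mat, energy) {
  if (mat$density == 0) return(numeric(length(energy)))
  mass_attenuation(mat, energy) * mat$density / 10
}

#' Theoretical electron density
#'
#' Electron density in the reporting convention used throughout the package:
#' 2 * rho * sum_i w_i Z_i / A_i, i.e. electrons per cm^3 in units of N_A/2.
#' In this convention water at 1.000 g/cm^3 is 1.1102 and graphite at
#' 1.700 g/cm^3 is 1.6984. Multiply by N_A/2 (`electrons_per_cm3()`) for
#' absolute electrons/cm^3.
#'
#' @param mat A `material`.
#' @return Electron density (dimensionless in the N_A/2 convention).
#' @export
electron_density <- function(mat) {
  stopifnot(inherits(mat, "material"))
  zia <- vapply(names(mat$composition), function(el) {
    row <- .element_constants[.element_constants$symbol == el, ]
    row$Z / row$A
  }, numeric(1))
  2 * mat$density * sum(mat$composition * zia)
}

#' Convert N_A/2-convention electron density to electrons per cm^3
#'
#' @param rho_e Electron density in the N_A/2 convention.
#' @return Electrons per cm^3.
#' @export
electrons_per_cm3 <- function(rho_e) rho_e * 6.02214076e23 / 2

#' Basis-material pair
#'
#' The two basis materials of the decomposition (tissue-like graphite and
#' bone-like aluminium by default) together with their electron densities.
#' The first material must be the less electron-dense one.
#'
#' @param material1,material2 `material` objects (defaults: registry
#'   graphite and aluminum).
#' @return An object of class `basis_pair` with fields `material1`,
#'   `material2`, `rho_e1`, `rho_e2`.
#' @export
basis_pair <- function(material1 = get_material("graphite"),
                       material2 = get_material("aluminum")) {
  r1 <- electron_density(material1)
  r2 <- electron_density(material2)
  if (!(r1 > 0 && r2 > 0 && r1 < r2)) {
    stop("basis pair requires 0 < rho_e1 < rho_e2 (tissue-like first)",
         call. = FALSE)
  }
  structure(list(material1 = material1, material2 = material2,
                 rho_e1 = r1, rho_e2 = r2),
            class = "basis_pair")
}

#' @export
print.basis_pair <- function(x, ...) {
  cat(sprintf("<basis_pair> %s (rho_e %.4f)  /  %s (rho_e %.4f)\n",
              x$material1$name, x$rho_e1, x$material2$name, x$rho_e2))
  invisible(x)
}
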