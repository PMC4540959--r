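#' Polychromatic X-ray spectrum
#'
#' Constructor for a normalized fluence spectrum on a keV grid. Weights are
#' normalized to sum to 1; bins above the peak tube potential must be zero.
#'
#' @param energies Energy grid in keV (ascending).
#' @param weights Relative fluence per bin (non-negative, not all zero).
#' @param kvp Peak tube potential in kV (== max photon energy in keV).
#' @param description Provenance string (model, filtration).
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(energies, weights, kvp,
                     description = "user-defined") {
  stopifnot(length(energies) == length(weights), all(diff(energies) > 0))
  if (any(weights < 0)) stop("negative spectrum weights", call. = FALSE)
  tot <- sum(weights)
  if (tot <= 0) stop("degenerate spectrum: all weights zero", call. = FALSE)
  if (any(weights[energies > kvp + 1e-9] > 0)) {
    stop("nonzero fluence above the peak tube potential", call. = FALSE)
  }
  structure(list(energies = energies, weights = weights / tot,
                 kvp = kvp, description = description),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %d kVp, %d bins [%g, %g] keV, mean %.2f keV\n",
              round(x$kvp), length(x$energies), min(x$energies),
              max(x$energies), mean_energy(x)))
  cat("  ", x$description, "\n")
  invisible(x)
}

#' Generate a bremsstrahlung tube spectrum
#'
#' Kramers-law tungsten-anode model N(E) proportional to (kVp - E)/E on a
#' 1 keV grid from 10 keV to the peak potential, hardened by the stated
#' inherent aluminium filtration (Beer-Lambert with the packaged Al table).
#' Characteristic lines are not modelled; the projection-domain look-up
#' table absorbs residual spectrum-model error by construction.
#'
#' @param kvp Peak tube potential, 40--150 kV.
#' @param inherent_filtration_mm_al Inherent filtration in mm of aluminium
#'   (default 2.5).
#' @param bin_keV Energy bin width in keV (default 1).
#' @return A normalized `spectrum`.
#' @examples
#' s <- generate_spectrum(120)
#' mean_energy(s)
#' @export
generate_spectrum <- function(kvp, inherent_filtration_mm_al = 2.5,
                              bin_keV = 1) {
  if (kvp < 40 || kvp > 150) {
    stop("kvp out of supported range [40, 150]", call. = FALSE)
  }
  if (inherent_filtration_mm_al < 0) {
    stop("filtration must be >= 0", call. = FALSE)
  }
  energies <- seq(10, kvp, by = bin_keV)
  w <- pmax(kvp - energies, 0) / energies
  s <- spectrum(energies, w, kvp,
                description = sprintf("Kramers %g kVp, unfiltered", kvp))
  if (inherent_filtration_mm_al > 0) {
    s <- filter_spectrum(s, get_material("aluminum"),
                         inherent_filtration_mm_al)
  }
  s$description <- sprintf("Kramers %g kVp + %.3g mm Al inherent filtration",
                           kvp, inherent_filtration_mm_al)
  s
}

#' Filter a spectrum through a material slab
#'
#' Multiplies each bin by exp(-mu(E) * thickness) and renormalizes.
#'
#' @param s A `spectrum`.
#' @param mat A `material`.
#' @param thickness_mm Slab thickness in mm (>= 0).
#' @return The hardened, renormalized `spectrum`.
#' @export
filter_spectrum <- function(s, mat, thickness_mm) {
  stopifnot(inherits(s, "spectrum"))
  if (thickness_mm < 0) stop("negative filter thickness", call. = FALSE)
  if (thickness_mm == 0) return(s)
  mu <- linear_attenuation(mat, s$energies)
  w <- s$weights * exp(-mu * thickness_mm)
  spectrum(s$energies, w, s$kvp,
           description = sprintf("%s + %.3g mm %s", s$description,
                                 thickness_mm, mat$name))
}

#' Mean energy of a spectrum
#'
#' Fluence-weighted mean photon energy, a convenient hardening diagnostic.
#'
#' @param s A `spectrum`.
#' @return Mean energy in keV.
#' @export
mean_energy <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  sum(s$weights * s$energies) / sum(s$weights)
}

#' Monochromatic (delta) spectrum
#'
#' Single-bin spectrum at `energy_keV`; with it the polychromatic projector
#' collapses to the monochromatic Beer-Lambert law, which makes it the
#' reference case for validation.
#'
#' @param energy_keV The single photon energy in keV.
#' @return A `spectrum` with one bin.
#' @export
delta_spectrum <- function(energy_keV) {
  spectrum(energy_keV, 1, kvp = energy_keV,
           description = sprintf("delta at %g keV", energy_keV))
}

#' Read a spectrum from a two-column text file
#'
#' Accepts whitespace- or comma-separated files with columns energy_keV and
#' relative fluence (e.g. exports from spectrum modelling GUIs). Lines
#' starting with '#' are ignored.
#'
#' @param path File path.
#' @param kvp Peak potential; defaults to the largest energy with nonzero
#'   fluence.
#' @return A normalized `spectrum`.
#' @export
read_spectrum <- function(path, kvp = NULL) {
  txt <- readLines(path)
  txt <- txt[!grepl("^\\s*(#|$)", txt)]
  parts <- lapply(strsplit(txt, "[,[:space:]]+"),
                  function(x) as.numeric(x[x != ""]))
  m <- do.call(rbind, parts)
  if (ncol(m) < 2) stop("expected two columns: energy_keV, fluence",
                        call. = FALSE)
  o <- order(m[, 1])
  e <- m[o, 1]; w <- m[o, 2]
  if (is.null(kvp)) kvp <- max(e[w > 0])
  spectrum(e, w, kvp, description = paste("file:", basename(path)))
}
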