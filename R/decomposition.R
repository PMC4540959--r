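# Two-slab polychromatic forward model and its Jacobian, vectorised over
# (d1, d2) pairs, for one spectrum. mu1/mu2 are linear attenuation (1/mm)
# on the spectrum grid. Returns list(g, J1, J2).
.slab_forward <- function(d1, d2, mu1, mu2, w, jacobian = FALSE) {
  T <- exp(-outer(d1, mu1) - outer(d2, mu2))
  I <- as.vector(T %*% w)
  out <- list(g = -log(I))
  if (jacobian) {
    out$J1 <- as.vector(T %*% (w * mu1)) / I
    out$J2 <- as.vector(T %*% (w * mu2)) / I
  }
  out
}

#' Build a dual-energy basis-decomposition look-up table
#'
#' Tabulates the forward map (d1, d2) -> (gH, gL) for X-ray paths through
#' d1 mm of the first and d2 mm of the second basis material under the two
#' scan spectra, using the same polychromatic model as the projector.
#' Because the forward values carry the full polychromatic (beam-hardening)
#' physics, inverting this table removes the hardening from the decomposed
#' projections by construction. The default grid extends to negative
#' thicknesses: the basis expansion is algebraic, and materials less
#' attenuating than the first basis material (e.g. polyethylene in a
#' graphite/aluminium basis) require d2 < 0.
#'
#' @param basis A `basis_pair`.
#' @param sH,sL High- and low-energy `spectrum` objects.
#' @param d1_grid,d2_grid Ascending thickness grids (mm) containing 0.
#' @return An object of class `decomp_lut` with the grids, the `gH`/`gL`
#'   tables (matrices `length(d1_grid) x length(d2_grid)`), the basis and
#'   cached per-spectrum attenuation vectors.
#' @export
build_lut <- function(basis, sH, sL,
                      d1_grid = seq(-50, 400, by = 2),
                      d2_grid = seq(-20, 60, by = 0.5)) {
  stopifnot(inherits(basis, "basis_pair"), inherits(sH, "spectrum"),
            inherits(sL, "spectrum"))
  if (any(diff(d1_grid) <= 0) || any(diff(d2_grid) <= 0)) {
    stop("thickness grids must be strictly ascending", call. = FALSE)
  }
  if (!any(d1_grid == 0) || !any(d2_grid == 0)) {
    stop("thickness grids must contain 0", call. = FALSE)
  }
  tab_for <- function(s) {
    mu1 <- linear_attenuation(basis$material1, s$energies)
    mu2 <- linear_attenuation(basis$material2, s$energies)
    A <- exp(-outer(d1_grid, mu1))            # n1 x nE
    B <- exp(-outer(d2_grid, mu2))            # n2 x nE
    I <- A %*% (s$weights * t(B))             # n1 x n2
    list(g = -log(I), mu1 = mu1, mu2 = mu2)
  }
  H <- tab_for(sH); L <- tab_for(sL)
  for (tb in list(H$g, L$g)) {
    if (any(apply(tb, 2, diff) <= 0) || any(apply(tb, 1, diff) <= 0)) {
      stop("computed LUT is not monotone in both thickness axes; ",
           "check the spectra", call. = FALSE)
    }
  }
  structure(list(d1_grid = d1_grid, d2_grid = d2_grid,
                 gH = H$g, gL = L$g, basis = basis, sH = sH, sL = sL,
                 mu = list(H1 = H$mu1, H2 = H$mu2,
                           L1 = L$mu1, L2 = L$mu2)),
            class = "decomp_lut")
}

#' @export
print.decomp_lut <- function(x, ...) {
  cat(sprintf(
    "<decomp_lut> %s/%s basis, d1 in [%g, %g] (%d), d2 in [%g, %g] (%d)\n",
    x$basis$material1$name, x$basis$material2$name,
    min(x$d1_grid), max(x$d1_grid), length(x$d1_grid),
    min(x$d2_grid), max(x$d2_grid), length(x$d2_grid)))
  cat(sprintf("  spectra: %g / %g kVp\n", x$sH$kvp, x$sL$kvp))
  invisible(x)
}

#' Evaluate the LUT's smooth forward model
#'
#' Computes (gH, gL) for arbitrary (off-grid, possibly negative) basis
#' thickness pairs with the same polychromatic model the table was built
#' from.
#'
#' @param lut A `decomp_lut`.
#' @param d1,d2 Thickness vectors (mm), equal length.
#' @return List with numeric vectors `gH`, `gL`.
#' @export
lut_forward <- function(lut, d1, d2) {
  list(gH = .slab_forward(d1, d2, lut$mu$H1, lut$mu$H2, lut$sH$weights)$g,
       gL = .slab_forward(d1, d2, lut$mu$L1, lut$mu$L2, lut$sL$weights)$g)
}

#' Invert dual-energy projections into basis thicknesses
#'
#' Solves the two-slab forward model for (d1, d2) given measured (gH, gL):
#' the linearised system at the origin (spectrum-averaged attenuation
#' coefficients, i.e. the forward Jacobian at zero thickness) provides the
#' initial guess and a damped 2-D Newton iteration with the analytic
#' polychromatic Jacobian refines it to |residual| < `tol` in g. Solutions
#' off the table grid and negative thicknesses are supported. Pixels that
#' fail to converge within `max_iter` iterations are clamped to the nearest
#' admissible thickness range and counted in the `n_nonconverged`
#' attribute - never silently.
#'
#' @param lut A `decomp_lut`.
#' @param gH,gL Measured log-projection vectors (equal length, finite).
#' @param tol Convergence tolerance on max(|gH - g|, |gL - g|)
#'   (default 1e-6).
#' @param max_iter Maximum Newton iterations (default 50).
#' @return List with vectors `d1`, `d2` (mm); attribute `n_nonconverged`.
#' @export
invert_pair <- function(lut, gH, gL, tol = 1e-6, max_iter = 50L) {
  stopifnot(length(gH) == length(gL), all(is.finite(gH)),
            all(is.finite(gL)))
  n <- length(gH)
  # linearised initial guess from the Jacobian at the origin
  a11 <- sum(lut$sH$weights * lut$mu$H1)
  a12 <- sum(lut$sH$weights * lut$mu$H2)
  a21 <- sum(lut$sL$weights * lut$mu$L1)
  a22 <- sum(lut$sL$weights * lut$mu$L2)
  det0 <- a11 * a22 - a12 * a21
  if (abs(det0) < 1e-12) {
    stop("spectra are not energy-separated: singular linearised system",
         call. = FALSE)
  }
  d1 <- (a22 * gH - a12 * gL) / det0
  d2 <- (-a21 * gH + a11 * gL) / det0
  span1 <- diff(range(lut$d1_grid)); span2 <- diff(range(lut$d2_grid))
  lim1 <- range(lut$d1_grid) + c(-0.5, 0.5) * span1
  lim2 <- range(lut$d2_grid) + c(-0.5, 0.5) * span2
  clamp <- function(x, lim) pmin(pmax(x, lim[1]), lim[2])
  d1 <- clamp(d1, lim1); d2 <- clamp(d2, lim2)

  active <- seq_len(n)
  converged <- logical(n)
  lambda <- rep(1, n)          # per-pixel damping factor
  resnorm <- rep(Inf, n)
  for (iter in seq_len(max_iter)) {
    fH <- .slab_forward(d1[active], d2[active], lut$mu$H1, lut$mu$H2,
                        lut$sH$weights, jacobian = TRUE)
    fL <- .slab_forward(d1[active], d2[active], lut$mu$L1, lut$mu$L2,
                        lut$sL$weights, jacobian = TRUE)
    rH <- gH[active] - fH$g
    rL <- gL[active] - fL$g
    resnorm[active] <- pmax(abs(rH), abs(rL))
    done <- resnorm[active] < tol
    converged[active[done]] <- TRUE
    if (all(done)) { active <- integer(0); break }
    keep <- !done
    active <- active[keep]
    rH <- rH[keep]; rL <- rL[keep]
    det <- fH$J1[keep] * fL$J2[keep] - fH$J2[keep] * fL$J1[keep]
    det[abs(det) < 1e-300] <- 1e-300
    s1 <- (fL$J2[keep] * rH - fH$J2[keep] * rL) / det
    s2 <- (-fL$J1[keep] * rH + fH$J1[keep] * rL) / det
    # additionally limit the raw step to half the table span
    fac <- pmax(1, pmax(abs(s1) / (0.5 * span1), abs(s2) / (0.5 * span2)))
    c1 <- clamp(d1[active] + lambda[active] * s1 / fac, lim1)
    c2 <- clamp(d2[active] + lambda[active] * s2 / fac, lim2)
    cH <- .slab_forward(c1, c2, lut$mu$H1, lut$mu$H2, lut$sH$weights)$g
    cL <- .slab_forward(c1, c2, lut$mu$L1, lut$mu$L2, lut$sL$weights)$g
    cres <- pmax(abs(gH[active] - cH), abs(gL[active] - cL))
    better <- is.finite(cres) & cres <= resnorm[active]
    ia <- active[better]
    d1[ia] <- c1[better]; d2[ia] <- c2[better]
    lambda[ia] <- pmin(1, lambda[ia] * 2)
    iw <- active[!better]
    lambda[iw] <- lambda[iw] / 2   # backtrack: retry with smaller step
  }
  out <- list(d1 = d1, d2 = d2)
  attr(out, "n_nonconverged") <- sum(!converged)
  out
}

#' Decompose dual-energy projection sets into basis projections
#'
#' Element-wise inversion of matched high/low-energy projection sets into
#' equivalent basis-material path lengths (B1, B2). Rays with gH = gL = 0
#' (misses) map to (0, 0) without iteration.
#'
#' @param projH,projL `projection_set` objects sharing geometry and angle
#'   ordering.
#' @param lut A `decomp_lut` built with the matching spectra.
#' @param chunk Pixels per vectorised Newton block (memory/speed knob).
#' @return An object of class `basis_projections`: `B1`, `B2` arrays with
#'   the projection dimensions, `geometry`, provenance, and
#'   `n_nonconverged` count.
#' @export
decompose <- function(projH, projL, lut, chunk = 40000L) {
  stopifnot(inherits(projH, "projection_set"),
            inherits(projL, "projection_set"),
            inherits(lut, "decomp_lut"))
  if (!identical(dim(projH$values), dim(projL$values)) ||
      !isTRUE(all.equal(projH$geometry[c("sad", "sdd", "pixel_size")],
                        projL$geometry[c("sad", "sdd", "pixel_size")]))) {
    stop("high/low projection sets have mismatched geometry", call. = FALSE)
  }
  gH <- as.vector(projH$values)
  gL <- as.vector(projL$values)
  B1 <- numeric(length(gH)); B2 <- numeric(length(gH))
  todo <- which(gH != 0 | gL != 0)
  nbad <- 0L
  for (start in seq_len(ceiling(length(todo) / chunk)) * chunk - chunk + 1L) {
    idx <- todo[start:min(start + chunk - 1L, length(todo))]
    sol <- invert_pair(lut, gH[idx], gL[idx])
    B1[idx] <- sol$d1; B2[idx] <- sol$d2
    nbad <- nbad + attr(sol, "n_nonconverged")
  }
  if (nbad > 0) {
    message("decompose: ", nbad, " pixel(s) did not reach the Newton ",
            "tolerance (clamped to nearest admissible thickness)")
  }
  structure(list(B1 = array(B1, dim = dim(projH$values)),
                 B2 = array(B2, dim = dim(projH$values)),
                 geometry = projH$geometry,
                 provenance = sprintf("decomposed: [%s] / [%s]",
                                      projH$spectrum_id, projL$spectrum_id),
                 n_nonconverged = nbad),
            class = "basis_projections")
}

#' @export
print.basis_projections <- function(x, ...) {
  d <- dim(x$B1)
  cat(sprintf("<basis_projections> %d x %d x %d, B1 in [%.3g, %.3g] mm, ",
              d[1], d[2], d[3], min(x$B1), max(x$B1)))
  cat(sprintf("B2 in [%.3g, %.3g] mm\n", min(x$B2), max(x$B2)))
  if (x$n_nonconverged > 0) {
    cat("  non-converged pixels:", x$n_nonconverged, "\n")
  }
  invisible(x)
}
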