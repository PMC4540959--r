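#' Polychromatic forward projection
#'
#' Simulates the log-attenuation projections of an analytic phantom for a
#' polychromatic spectrum: for each detector pixel the exact per-material
#' chord lengths d_m are computed and
#' \deqn{g = -\ln \sum_E S(E)\, \exp(-\sum_m \mu_m(E)\, d_m),}
#' with the energy sum taken over the spectrum bins (rectangle rule; the
#' spectrum is defined per bin). Noiseless and deterministic; the sign
#' convention g = -ln(I/I0) >= 0 is recorded on the result.
#'
#' @param phantom A `phantom_spec`.
#' @param geom A `scan_geometry`.
#' @param s A normalized `spectrum` covering the attenuation-table range.
#' @return An object of class `projection_set`: list with `values` (array
#'   `n_projections x det_rows x det_cols`), `geometry`, `spectrum_id`,
#'   `kvp` and `convention`.
#' @export
polychromatic_projection <- function(phantom, geom, s) {
  stopifnot(inherits(phantom, "phantom_spec"),
            inherits(geom, "scan_geometry"), inherits(s, "spectrum"))
  if (abs(sum(s$weights) - 1) > 1e-9) {
    stop("spectrum is not normalized", call. = FALSE)
  }
  # linear attenuation (1/mm) of every phantom material on the spectrum grid
  all_mats <- c(list(phantom$background$material),
                lapply(phantom$inserts, function(i) i$material))
  mu_of <- function(m) linear_attenuation(m, s$energies)
  betas <- .projection_angles(geom)
  vals <- array(0, dim = c(geom$n_projections, geom$det_rows,
                           geom$det_cols))
  w <- s$weights
  for (k in seq_along(betas)) {
    dp <- .detector_points(geom, betas[k])
    D <- .path_length_matrix(phantom, dp$src, dp$pts)
    mats <- attr(D, "materials")
    Mu <- matrix(vapply(mats, mu_of, numeric(length(s$energies))),
                 nrow = length(s$energies))               # nE x nmat
    g <- -log(as.vector(exp(-D %*% t(Mu)) %*% w))
    g[rowSums(D) == 0] <- 0
    vals[k, , ] <- matrix(g, nrow = geom$det_rows, byrow = TRUE)
  }
  structure(list(values = vals, geometry = geom,
                 spectrum_id = s$description, kvp = s$kvp,
                 convention = "g = -ln(I/I0)"),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<projection_set> %d x %d x %d (proj x rows x cols), %s\n",
              d[1], d[2], d[3], x$convention))
  cat("  spectrum:", x$spectrum_id, "\n")
  cat(sprintf("  g range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Add Poisson counting noise to a projection set
#'
#' Resamples the transmitted intensity I0 exp(-g) with Poisson statistics
#' at the stated incident photon count per ray and re-logs. Counts of zero
#' are clamped to one photon before the logarithm. The default simulation
#' pipeline is noiseless; this exists for robustness studies.
#'
#' @param p A `projection_set`.
#' @param photons_per_ray Incident photons per detector pixel (> 0).
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @return A new `projection_set` with noisy values.
#' @export
add_poisson_noise <- function(p, photons_per_ray, seed = 1L) {
  stopifnot(inherits(p, "projection_set"))
  if (photons_per_ray <= 0) {
    stop("photons_per_ray must be > 0", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lambda <- photons_per_ray * exp(-p$values)
  n <- length(lambda)
  # rpois overflows 32-bit counts at very large means; switch to the
  # normal limit where the approximation error is far below shot noise
  counts <- numeric(n)
  big <- lambda > 1e7
  counts[big] <- round(stats::rnorm(sum(big), lambda[big],
                                    sqrt(lambda[big])))
  counts[!big] <- stats::rpois(sum(!big), lambda[!big])
  counts <- pmax(counts, 1)
  out <- p
  out$values <- array(-log(counts / photons_per_ray), dim = dim(p$values))
  out$spectrum_id <- sprintf("%s + Poisson(%g photons, seed %d)",
                             p$spectrum_id, photons_per_ray, seed)
  out
}
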