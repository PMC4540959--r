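#' Reconstruction grid description
#'
#' In-plane grid of `n x n` voxels centered on the isocenter; `nz` slices
#' at `z_spacing` (fan-beam mode reconstructs the single central slice).
#'
#' @param n In-plane voxel count per axis.
#' @param voxel_size Isotropic in-plane voxel size (mm).
#' @param nz Number of axial slices (default 1, centered at z = 0).
#' @param z_spacing Axial spacing (mm); defaults to `voxel_size`.
#' @return A list used by [fdk_reconstruct()].
#' @export
recon_grid <- function(n = 256, voxel_size = 1.0, nz = 1L,
                       z_spacing = voxel_size) {
  stopifnot(n > 0, voxel_size > 0, nz >= 1)
  list(n = as.integer(n), voxel_size = voxel_size, nz = as.integer(nz),
       z_spacing = z_spacing)
}

# Band-limited ramp (Ram-Lak) kernel sampled at spacing tau, length 2N-1.
.ramp_kernel <- function(N, tau) {
  n <- -(N - 1):(N - 1)
  h <- numeric(length(n))
  h[n == 0] <- 1 / (4 * tau^2)
  odd <- n %% 2 != 0
  h[odd] <- -1 / (pi^2 * n[odd]^2 * tau^2)
  h
}

# Filter rows of a matrix (nrows x ncols) with the ramp kernel via FFT.
# Returns the filtered matrix scaled by tau (discrete convolution as
# integral approximation) and the fan-beam 1/2 factor.
.ramp_filter_rows <- function(m, tau, apodization = "none") {
  ncols <- ncol(m)
  L <- 2^ceiling(log2(2 * ncols))
  h <- .ramp_kernel(ncols, tau)
  hp <- numeric(L)
  hp[1:(2 * ncols - 1)] <- h
  H <- stats::fft(hp)
  if (apodization == "hann") {
    f <- seq(0, L - 1) / L
    f <- pmin(f, 1 - f) * 2        # 0..1, Nyquist at 1
    H <- H * 0.5 * (1 + cos(pi * f))
  }
  mp <- matrix(0, nrow(m), L)
  mp[, 1:ncols] <- m
  ft <- t(stats::mvfft(t(mp)))
  conv <- Re(t(stats::mvfft(t(ft * rep(H, each = nrow(m))),
                            inverse = TRUE))) / L
  0.5 * tau * conv[, (ncols):(2 * ncols - 1), drop = FALSE]
}

#' Filtered backprojection / FDK reconstruction
#'
#' Weighted filtered backprojection for the circular full-arc geometry:
#' cosine pre-weighting of each projection, row-wise band-limited ramp
#' filtering (no apodization by default), and distance-weighted
#' backprojection. With single-row projections this is the exact
#' flat-detector fan-beam FBP of the central slice; with multi-row
#' projections it is the standard FDK approximation. The operator is linear
#' in the input sinogram.
#'
#' @param p A `projection_set`, a `basis_projections` (give `channel`), or
#'   a numeric array `n_projections x det_rows x det_cols`.
#' @param geom A `scan_geometry` (taken from `p` when available).
#' @param grid A [recon_grid()].
#' @param channel For `basis_projections` input: "B1" or "B2".
#' @param quantity Quantity tag for the output volume (e.g. "mu", "b1",
#'   "b2"); defaults to "mu" for projection sets and the channel name for
#'   basis projections.
#' @param apodization "none" (default) or "hann".
#' @return An object of class `ct_volume`: `values` (matrix for one slice,
#'   3-D array otherwise), `voxel_size`, `origin`, `quantity`,
#'   `provenance`.
#' @export
fdk_reconstruct <- function(p, geom = NULL, grid = recon_grid(),
                            channel = NULL, quantity = NULL,
                            apodization = c("none", "hann")) {
  apodization <- match.arg(apodization)
  if (inherits(p, "projection_set")) {
    vals <- p$values
    if (is.null(geom)) geom <- p$geometry
    if (is.null(quantity)) quantity <- "mu"
    prov <- p$spectrum_id
  } else if (inherits(p, "basis_projections")) {
    if (is.null(channel) || !channel %in% c("B1", "B2")) {
      stop("give channel = \"B1\" or \"B2\" for basis projections",
           call. = FALSE)
    }
    vals <- p[[channel]]
    if (is.null(geom)) geom <- p$geometry
    if (is.null(quantity)) quantity <- tolower(sub("B", "b", channel))
    prov <- paste0(p$provenance, " [", channel, "]")
  } else {
    vals <- p
    if (is.null(geom)) stop("geom required for raw array input",
                            call. = FALSE)
    if (is.null(quantity)) quantity <- "mu"
    prov <- "raw array"
  }
  if (abs(geom$arc - 360) > 1e-9) {
    stop("only full 360-degree arcs are supported", call. = FALSE)
  }
  stopifnot(length(dim(vals)) == 3,
            dim(vals)[1] == geom$n_projections,
            dim(vals)[2] == geom$det_rows,
            dim(vals)[3] == geom$det_cols)

  D <- geom$sad
  scale <- geom$sad / geom$sdd            # detector -> isocenter plane
  tau <- geom$pixel_size * scale
  su <- (seq_len(geom$det_cols) - 1 - (geom$det_cols - 1) / 2) * tau
  sv <- (seq_len(geom$det_rows) - 1 - (geom$det_rows - 1) / 2) * tau
  W <- D / sqrt(D^2 + outer(sv^2, su^2, `+`))   # rows x cols cosine weight

  n <- grid$n
  xy <- (seq_len(n) - 1 - (n - 1) / 2) * grid$voxel_size
  zc <- (seq_len(grid$nz) - 1 - (grid$nz - 1) / 2) * grid$z_spacing
  X <- matrix(xy, n, n)                  # x varies along rows
  Y <- matrix(xy, n, n, byrow = TRUE)
  betas <- .projection_angles(geom)
  dbeta <- geom$angular_step * pi / 180
  out <- array(0, dim = c(n, n, grid$nz))

  for (k in seq_along(betas)) {
    beta <- betas[k]
    Q <- .ramp_filter_rows(matrix(vals[k, , ], geom$det_rows) * W, tau,
                           apodization)
    pcomp <- -X * sin(beta) + Y * cos(beta)   # toward-source component
    tcomp <- X * cos(beta) + Y * sin(beta)
    ratio <- D / (D - pcomp)
    sprime <- tcomp * ratio
    w2 <- ratio^2
    iu <- (sprime - su[1]) / tau + 1
    i0 <- floor(iu)
    fu <- iu - i0
    ok <- i0 >= 1 & i0 < geom$det_cols
    i0ok <- i0[ok]; fuok <- fu[ok]
    for (iz in seq_len(grid$nz)) {
      if (geom$det_rows == 1L) {
        q <- Q[1, ]
        acc <- matrix(0, n, n)
        acc[ok] <- (1 - fuok) * q[i0ok] + fuok * q[i0ok + 1]
      } else {
        vprime <- zc[iz] * ratio
        jv <- (vprime - sv[1]) / tau + 1
        j0 <- floor(jv)
        okz <- ok & j0 >= 1 & j0 < geom$det_rows
        j0z <- j0[okz]; fv <- (jv - j0)[okz]
        i0z <- i0[okz]; fuz <- fu[okz]
        acc <- matrix(0, n, n)
        acc[okz] <-
          (1 - fv) * ((1 - fuz) * Q[cbind(j0z, i0z)] +
                        fuz * Q[cbind(j0z, i0z + 1)]) +
          fv * ((1 - fuz) * Q[cbind(j0z + 1, i0z)] +
                  fuz * Q[cbind(j0z + 1, i0z + 1)])
      }
      out[, , iz] <- out[, , iz] + dbeta * w2 * acc
    }
  }
  values <- if (grid$nz == 1L) out[, , 1] else out
  structure(list(values = values, voxel_size = grid$voxel_size,
                 z_spacing = grid$z_spacing,
                 origin = c(xy[1], xy[1], zc[1]),
                 quantity = quantity,
                 provenance = sprintf(
                   "FBP/FDK %d views, ramp(%s), %s", geom$n_projections,
                   apodization, prov)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<ct_volume> [%s] %s @ %g mm voxels, range [%.4g, %.4g]\n",
              paste(d, collapse = " x "), x$quantity, x$voxel_size,
              min(x$values), max(x$values)))
  cat(" ", x$provenance, "\n")
  invisible(x)
}

#' Convert an attenuation volume to Hounsfield units
#'
#' HU = 1000 (mu - mu_water) / mu_water; water maps to 0 HU and vacuum to
#' -1000 HU.
#'
#' @param v A `ct_volume` with quantity "mu" (1/mm).
#' @param mu_water_ref Reference water attenuation in 1/mm (> 0), e.g. the
#'   value at the spectrum's effective energy.
#' @return A `ct_volume` with quantity "HU".
#' @export
to_hu <- function(v, mu_water_ref) {
  stopifnot(inherits(v, "ct_volume"))
  if (v$quantity != "mu") {
    stop("to_hu expects a volume with quantity 'mu'", call. = FALSE)
  }
  if (mu_water_ref <= 0) {
    stop("mu_water_ref must be > 0", call. = FALSE)
  }
  out <- v
  out$values <- 1000 * (v$values - mu_water_ref) / mu_water_ref
  out$quantity <- "HU"
  out$provenance <- sprintf("%s; HU ref mu_w = %g /mm", v$provenance,
                            mu_water_ref)
  out
}
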