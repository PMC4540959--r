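#' Electron-density image from basis-coefficient volumes
#'
#' Voxel-wise synthesis rho_e = b1 rho_e1 + b2 rho_e2 from the two
#' reconstructed basis-coefficient volumes, in the N_A/2 unit convention
#' (water = 1.1102).
#'
#' @param b1,b2 `ct_volume` objects on identical grids.
#' @param basis The `basis_pair` used for decomposition.
#' @return A `ct_volume` with quantity "rho_e".
#' @export
electron_density_image <- function(b1, b2, basis) {
  stopifnot(inherits(b1, "ct_volume"), inherits(b2, "ct_volume"),
            inherits(basis, "basis_pair"))
  if (!identical(dim(b1$values), dim(b2$values)) ||
      b1$voxel_size != b2$voxel_size) {
    stop("b1 and b2 volumes are on different grids", call. = FALSE)
  }
  out <- b1
  out$values <- b1$values * basis$rho_e1 + b2$values * basis$rho_e2
  out$quantity <- "rho_e"
  out$provenance <- sprintf("rho_e = b1*%.4f + b2*%.4f; %s", basis$rho_e1,
                            basis$rho_e2, b1$provenance)
  out
}

#' Rectangular region of interest
#'
#' @param center In-plane ROI center (x, y) in mm.
#' @param size ROI edge lengths (mm); scalar for a square (default 5 mm,
#'   the usual uniformity-protocol size).
#' @param slice Axial slice index for 3-D volumes (default central).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(center, size = 5, slice = NULL) {
  size <- rep(as.numeric(size), length.out = 2)
  stopifnot(all(size > 0), length(center) == 2)
  structure(list(center = as.numeric(center), size = size, slice = slice),
            class = "roi_spec")
}

# indices of voxel centers falling inside the ROI
.roi_slice_values <- function(v, roi) {
  vals <- v$values
  if (length(dim(vals)) == 3) {
    iz <- if (is.null(roi$slice)) (dim(vals)[3] + 1) %/% 2 else roi$slice
    vals <- vals[, , iz]
  }
  n <- dim(vals)
  xs <- v$origin[1] + (seq_len(n[1]) - 1) * v$voxel_size
  ys <- v$origin[2] + (seq_len(n[2]) - 1) * v$voxel_size
  ix <- which(abs(xs - roi$center[1]) <= roi$size[1] / 2)
  iy <- which(abs(ys - roi$center[2]) <= roi$size[2] / 2)
  if (!length(ix) || !length(iy) ||
      roi$center[1] - roi$size[1] / 2 < xs[1] - v$voxel_size / 2 ||
      roi$center[1] + roi$size[1] / 2 > xs[n[1]] + v$voxel_size / 2 ||
      roi$center[2] - roi$size[2] / 2 < ys[1] - v$voxel_size / 2 ||
      roi$center[2] + roi$size[2] / 2 > ys[n[2]] + v$voxel_size / 2) {
    stop("ROI extends outside the volume", call. = FALSE)
  }
  vals[ix, iy]
}

#' Mean voxel value inside an ROI
#'
#' Arithmetic mean over the voxels whose centers fall inside the ROI
#' rectangle.
#'
#' @param v A `ct_volume`.
#' @param roi An `roi_spec` fully inside the volume.
#' @return The ROI mean.
#' @export
roi_mean <- function(v, roi) {
  stopifnot(inherits(v, "ct_volume"), inherits(roi, "roi_spec"))
  mean(.roi_slice_values(v, roi))
}

#' Beam-hardening (cupping) metric
#'
#' BH = (mean of the peripheral ROI means - central ROI mean) /
#' central ROI mean x 100. Positive values indicate the classic cupping
#' profile (center depressed relative to the periphery). The metric is
#' scale-invariant but not shift-invariant, so apply it to a
#' physically-scaled image (attenuation, HU + 1000, or electron density),
#' not to near-zero water HU.
#'
#' @param v A `ct_volume`.
#' @param center_roi Central `roi_spec`.
#' @param periphery_rois List of exactly four peripheral `roi_spec`s.
#' @return The BH value in percent.
#' @export
beam_hardening_metric <- function(v, center_roi, periphery_rois) {
  if (length(periphery_rois) != 4) {
    stop("exactly four peripheral ROIs are required", call. = FALSE)
  }
  mc <- roi_mean(v, center_roi)
  mp <- vapply(periphery_rois, function(r) roi_mean(v, r), numeric(1))
  if (abs(mc) < 1e-9 * max(abs(v$values), 1e-300)) {
    stop("undefined beam-hardening metric: central ROI mean is ~0 ",
         "(apply the metric on an attenuation-proportional scale)",
         call. = FALSE)
  }
  (mean(mp) - mc) / mc * 100
}

#' Default cupping-evaluation ROI layout
#'
#' One central ROI on the axis and four peripheral ROIs at
#' `frac` of the cylinder radius at 0/90/180/270 degrees.
#'
#' @param radius Cylinder radius (mm).
#' @param size ROI edge length (mm).
#' @param frac Radial position of the peripheral ROIs (default 0.8).
#' @return List with `center` and `periphery` (list of 4).
#' @export
default_bh_rois <- function(radius, size = 5, frac = 0.8) {
  ang <- c(0, 90, 180, 270) * pi / 180
  list(center = roi_spec(c(0, 0), size),
       periphery = lapply(ang, function(a) {
         roi_spec(frac * radius * c(cos(a), sin(a)), size)
       }))
}

#' Evaluate a reconstructed electron-density volume against theory
#'
#' Places one ROI at the center of each phantom insert and one in the
#' background material, compares the ROI means with the theoretical
#' electron densities (2 rho sum w Z/A convention) and reports per-material
#' percent errors and the Pearson correlation between calculated and
#' theoretical values.
#'
#' @param rho_e A `ct_volume` with quantity "rho_e".
#' @param phantom The `phantom_spec` that was imaged.
#' @param rois Optional named list of `roi_spec`s overriding the automatic
#'   placement (names must be material names).
#' @param roi_size ROI edge length in mm for automatic placement.
#' @return An object of class `de_report`: a data frame with columns
#'   `material`, `calculated`, `theoretical`, `error_pct`, plus attribute
#'   `correlation`.
#' @export
evaluate_virtual_phantom <- function(rho_e, phantom, rois = NULL,
                                     roi_size = 5) {
  stopifnot(inherits(rho_e, "ct_volume"), inherits(phantom, "phantom_spec"))
  if (is.null(rois)) {
    rois <- lapply(phantom$inserts, function(ins) {
      roi_spec(ins$center, roi_size)
    })
    names(rois) <- vapply(phantom$inserts, function(i) i$material$name,
                          character(1))
    rois[[phantom$background$material$name]] <-
      roi_spec(phantom$background$center, roi_size)
  }
  mats <- c(lapply(phantom$inserts, function(i) i$material),
            list(phantom$background$material))
  names(mats) <- vapply(mats, function(m) m$name, character(1))
  rows <- lapply(names(rois), function(nm) {
    if (is.null(mats[[nm]])) {
      stop("no material (hence no theoretical rho_e) named '", nm, "'",
           call. = FALSE)
    }
    calc <- roi_mean(rho_e, rois[[nm]])
    theor <- electron_density(mats[[nm]])
    data.frame(material = nm, calculated = calc, theoretical = theor,
               error_pct = abs(calc - theor) / theor * 100)
  })
  rep <- do.call(rbind, rows)
  attr(rep, "correlation") <- stats::cor(rep$calculated, rep$theoretical)
  class(rep) <- c("de_report", "data.frame")
  rep
}

#' @export
print.de_report <- function(x, digits = 4, ...) {
  cat("Electron-density evaluation (N_A/2 units)\n")
  df <- as.data.frame(x)
  df$calculated <- round(df$calculated, digits)
  df$theoretical <- round(df$theoretical, digits)
  df$error_pct <- round(df$error_pct, 2)
  print(df, row.names = FALSE)
  cat(sprintf("Pearson correlation (calculated vs theoretical): %.4f\n",
              attr(x, "correlation")))
  invisible(x)
}
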