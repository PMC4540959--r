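#' Cone/fan-beam scan geometry
#'
#' Circular full-arc acquisition geometry. Coordinates: isocenter origin,
#' millimetres, right-handed; the source rotates counter-clockwise starting
#' on the +y axis; the flat detector is perpendicular to the central ray
#' with 0-based pixel indices addressing pixel centers. With `det_rows = 1`
#' the geometry describes the central-slice fan-beam mode.
#'
#' @param sad Source-to-axis distance (mm).
#' @param sdd Source-to-detector distance (mm), > sad.
#' @param det_cols,det_rows Detector pixel counts.
#' @param pixel_size Detector pixel pitch (mm).
#' @param n_projections Number of projections over the arc.
#' @param arc Scan arc in degrees (only 360 supported downstream).
#' @param angular_step Angular increment in degrees; must equal
#'   `arc / n_projections` when given.
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(sad = 1000, sdd = 1536, det_cols = 512,
                          det_rows = 1, pixel_size = 1.0,
                          n_projections = 600, arc = 360,
                          angular_step = NULL) {
  if (!(sad > 0 && sdd > sad)) stop("need 0 < sad < sdd", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  if (n_projections < 1) stop("need at least one projection", call. = FALSE)
  step <- arc / n_projections
  if (!is.null(angular_step) && abs(angular_step - step) > 1e-6) {
    stop(sprintf(
      "inconsistent geometry: %d projections x %g deg != %g deg arc",
      n_projections, angular_step, arc), call. = FALSE)
  }
  structure(list(sad = sad, sdd = sdd, det_cols = as.integer(det_cols),
                 det_rows = as.integer(det_rows), pixel_size = pixel_size,
                 n_projections = as.integer(n_projections),
                 angular_step = step, arc = arc),
            class = "scan_geometry")
}

#' Build a scan geometry from a configuration list
#'
#' Thin wrapper around [scan_geometry()] accepting a named list (e.g. the
#' `geometry` block of a YAML pipeline config).
#'
#' @param config Named list of `scan_geometry` arguments; missing keys take
#'   the defaults.
#' @return A `scan_geometry`.
#' @export
make_geometry <- function(config = list()) {
  do.call(scan_geometry, config)
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf(
    "<scan_geometry> SAD %g / SDD %g mm (mag %.3f), %dx%d px @ %g mm,\n",
    x$sad, x$sdd, x$sdd / x$sad, x$det_rows, x$det_cols, x$pixel_size))
  cat(sprintf("  %d projections, %g deg steps over %g deg\n",
              x$n_projections, x$angular_step, x$arc))
  invisible(x)
}

#' Analytic cylinder phantom
#'
#' A water-like background cylinder with nested cylindrical inserts, all
#' axes parallel to z. Inserts must lie strictly inside the background and
#' must not overlap each other.
#'
#' @param background List with `material`, `center` (xy, mm), `radius`
#'   (mm), and `height` (axial extent, mm).
#' @param inserts List of inserts, each a list with `material`, `center`,
#'   `radius` and optionally `height` (defaults to the background height).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(background, inserts = list()) {
  background$center <- as.numeric(background$center)
  if (is.null(background$height)) background$height <- 200
  stopifnot(inherits(background$material, "material"),
            background$radius > 0, background$height > 0)
  inserts <- lapply(inserts, function(ins) {
    ins$center <- as.numeric(ins$center)
    if (is.null(ins$height)) ins$height <- background$height
    stopifnot(inherits(ins$material, "material"), ins$radius > 0)
    d <- sqrt(sum((ins$center - background$center)^2))
    if (d + ins$radius >= background$radius) {
      stop("insert '", ins$material$name,
           "' is not strictly inside the background cylinder", call. = FALSE)
    }
    ins
  })
  if (length(inserts) > 1) {
    for (i in seq_len(length(inserts) - 1)) {
      for (j in (i + 1):length(inserts)) {
        d <- sqrt(sum((inserts[[i]]$center - inserts[[j]]$center)^2))
        if (d < inserts[[i]]$radius + inserts[[j]]$radius) {
          stop("inserts ", i, " and ", j, " overlap", call. = FALSE)
        }
      }
    }
  }
  structure(list(background = background, inserts = inserts),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s cylinder r = %g mm, %d insert(s)\n",
              x$background$material$name, x$background$radius,
              length(x$inserts)))
  for (ins in x$inserts) {
    cat(sprintf("  %-10s r = %g mm at (%+g, %+g)\n", ins$material$name,
                ins$radius, ins$center[1], ins$center[2]))
  }
  invisible(x)
}

#' Virtual electron-density phantom
#'
#' The simulation phantom: a 256 mm diameter water cylinder with four
#' 20 mm radius cylindrical inserts (silicon, PMMA, polyethylene, graphite)
#' centered 64 mm from the axis at 0, 90, 180 and 270 degrees
#' (counter-clockwise from +x).
#'
#' @param insert_radius Insert radius in mm (default 20).
#' @param insert_offset Insert center distance from the axis in mm
#'   (default 64).
#' @return A `phantom_spec`.
#' @export
build_virtual_phantom <- function(insert_radius = 20, insert_offset = 64) {
  mats <- list(get_material("silicon"), get_material("pmma"),
               get_material("pe"), get_material("graphite"))
  ang <- c(0, 90, 180, 270) * pi / 180
  inserts <- lapply(seq_along(mats), function(i) {
    list(material = mats[[i]],
         center = insert_offset * c(cos(ang[i]), sin(ang[i])),
         radius = insert_radius)
  })
  phantom_spec(
    background = list(material = get_material("water"),
                      center = c(0, 0), radius = 128),
    inserts = inserts)
}

#' Uniform water cylinder phantom
#'
#' Water-equivalent uniformity module (150 mm diameter by default), used
#' for beam-hardening/cupping evaluation.
#'
#' @param diameter Cylinder diameter in mm.
#' @return A `phantom_spec` with no inserts.
#' @export
build_uniformity_phantom <- function(diameter = 150) {
  phantom_spec(background = list(material = get_material("water"),
                                 center = c(0, 0), radius = diameter / 2))
}

# Chord lengths of z-aligned cylinders along rays from a single source to
# many detector points. `pts` is an n x 3 matrix. Returns a vector of mm.
.cyl_chords <- function(center, radius, height, src, pts) {
  dx <- pts[, 1] - src[1]
  dy <- pts[, 2] - src[2]
  dz <- pts[, 3] - src[3]
  nrm <- sqrt(dx^2 + dy^2 + dz^2)
  ox <- src[1] - center[1]
  oy <- src[2] - center[2]
  a <- dx^2 + dy^2
  b <- 2 * (ox * dx + oy * dy)
  cc <- ox^2 + oy^2 - radius^2
  disc <- b^2 - 4 * a * cc
  hit <- disc > 0 & a > 0
  chord <- numeric(nrow(pts))
  if (!any(hit)) return(chord)
  sq <- sqrt(pmax(disc[hit], 0))
  t1 <- (-b[hit] - sq) / (2 * a[hit])
  t2 <- (-b[hit] + sq) / (2 * a[hit])
  # clip the parametric interval by the axial extent of the cylinder
  zmin <- -height / 2; zmax <- height / 2
  dzh <- dz[hit]; z0 <- src[3]
  tlo <- t1; thi <- t2
  nz <- abs(dzh) > 1e-12
  if (any(nz)) {
    za <- (zmin - z0) / dzh[nz]
    zb <- (zmax - z0) / dzh[nz]
    zl <- pmin(za, zb); zh <- pmax(za, zb)
    tlo[nz] <- pmax(tlo[nz], zl)
    thi[nz] <- pmin(thi[nz], zh)
  }
  if (any(!nz) && (z0 < zmin || z0 > zmax)) {
    tlo[!nz] <- 0; thi[!nz] <- 0
  }
  chord[hit] <- pmax(thi - tlo, 0) * nrm[hit]
  chord
}

# Per-material path-length matrix for rays from `src` to points `pts`
# (n x 3). Background length = background chord - sum of insert chords.
# Returns an n x n_materials matrix with materials as attribute.
.path_length_matrix <- function(phantom, src, pts) {
  bg <- phantom$background
  bg_chord <- .cyl_chords(bg$center, bg$radius, bg$height, src, pts)
  mats <- list(bg$material)
  cols <- list(bg_chord)
  for (ins in phantom$inserts) {
    ch <- .cyl_chords(ins$center, ins$radius, ins$height, src, pts)
    cols[[1]] <- cols[[1]] - ch
    idx <- which(vapply(mats, function(m) identical(m, ins$material),
                        logical(1)))
    if (length(idx)) {
      cols[[idx[1]]] <- cols[[idx[1]]] + ch
    } else {
      mats[[length(mats) + 1L]] <- ins$material
      cols[[length(cols) + 1L]] <- ch
    }
  }
  D <- do.call(cbind, cols)
  D[D < 0] <- 0  # guard against roundoff at tangency
  attr(D, "materials") <- mats
  D
}

#' Exact per-material path lengths along one ray
#'
#' Computes the intersection lengths of a source-to-detector ray with each
#' material region of an analytic cylinder phantom (exact line-cylinder
#' chords; the background length is its chord minus the traversed insert
#' chords).
#'
#' @param phantom A `phantom_spec`.
#' @param source Ray origin, length-3 numeric (mm).
#' @param point A second point on the ray (e.g. detector pixel center), mm.
#' @return Named numeric vector of path lengths in mm per material (named
#'   by material name); rays missing the phantom give all zeros.
#' @export
ray_path_lengths <- function(phantom, source, point) {
  source <- as.numeric(source); point <- as.numeric(point)
  if (length(source) == 2) source <- c(source, 0)
  if (length(point) == 2) point <- c(point, 0)
  if (all(source == point)) stop("degenerate ray", call. = FALSE)
  D <- .path_length_matrix(phantom, source, matrix(point, nrow = 1))
  mats <- attr(D, "materials")
  stats::setNames(as.numeric(D[1, ]),
                  vapply(mats, function(m) m$name, character(1)))
}

# Source position and detector pixel-center positions for projection angle
# beta (radians). Returns list(src, pts) with pts (rows*cols) x 3 ordered
# column-major over (col within row? -> cols vary fastest within each row).
.detector_points <- function(geom, beta) {
  es <- c(-sin(beta), cos(beta), 0)       # unit vector toward source
  uhat <- c(cos(beta), sin(beta), 0)      # detector column axis
  src <- geom$sad * es
  dc <- -(geom$sdd - geom$sad) * es
  u <- (seq_len(geom$det_cols) - 1 - (geom$det_cols - 1) / 2) *
    geom$pixel_size
  v <- (seq_len(geom$det_rows) - 1 - (geom$det_rows - 1) / 2) *
    geom$pixel_size
  pu <- rep(u, times = geom$det_rows)
  pv <- rep(v, each = geom$det_cols)
  pts <- cbind(dc[1] + pu * uhat[1], dc[2] + pu * uhat[2], pv)
  list(src = src, pts = pts)
}

.projection_angles <- function(geom) {
  (seq_len(geom$n_projections) - 1) * geom$angular_step * pi / 180
}
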