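# shared fixtures: small geometries and a memo cache so expensive
# simulations are computed once per test run
.memo <- new.env(parent = emptyenv())

memoize <- function(key, compute) {
  if (is.null(.memo[[key]])) .memo[[key]] <- compute()
  .memo[[key]]
}

water <- function() get_material("water")
graphite <- function() get_material("graphite")

small_fan_geom <- function(det_cols = 128, n_projections = 90) {
  scan_geometry(det_cols = det_cols, det_rows = 1, pixel_size = 1.0,
                n_projections = n_projections)
}

# detector pixel centers recomputed from the documented convention,
# independent of the package internals (for projector oracles)
oracle_detector <- function(geom, beta) {
  es <- c(-sin(beta), cos(beta))
  uhat <- c(cos(beta), sin(beta))
  src <- geom$sad * es
  dc <- -(geom$sdd - geom$sad) * es
  u <- (seq_len(geom$det_cols) - 1 - (geom$det_cols - 1) / 2) *
    geom$pixel_size
  list(src = src,
       px = dc[1] + u * uhat[1],
       py = dc[2] + u * uhat[2])
}

# chord of a circle (center cx,cy radius r) along the ray src -> (px,py),
# from the analytic perpendicular-distance formula
oracle_chord <- function(src, px, py, cx, cy, r) {
  dx <- px - src[1]; dy <- py - src[2]
  nrm <- sqrt(dx^2 + dy^2)
  h <- abs(dx * (src[2] - cy) - dy * (src[1] - cx)) / nrm
  ifelse(h < r, 2 * sqrt(pmax(r^2 - h^2, 0)), 0)
}

desk_result <- function() {
  memoize("desk", function() {
    suppressMessages(run_pipeline(pipeline_config()))
  })
}

uniformity_result <- function() {
  memoize("uniformity", function() {
    suppressMessages(run_pipeline(
      pipeline_config(phantom = build_uniformity_phantom(150))))
  })
}
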