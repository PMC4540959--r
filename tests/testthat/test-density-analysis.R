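mk_volume <- function(values, voxel = 1, quantity = "rho_e") {
  n <- dim(values)
  structure(list(values = values, voxel_size = voxel, z_spacing = voxel,
                 origin = c(-(n[1] - 1) / 2 * voxel,
                            -(n[2] - 1) / 2 * voxel, 0),
                 quantity = quantity, provenance = "synthetic"),
            class = "ct_volume")
}

test_that("electron-density synthesis is the voxel-wise basis expansion", {
  basis <- basis_pair()
  ones <- mk_volume(matrix(1, 16, 16), quantity = "b1")
  zeros <- mk_volume(matrix(0, 16, 16), quantity = "b2")
  v <- electron_density_image(ones, zeros, basis)
  expect_true(all(abs(v$values - basis$rho_e1) < 1e-12))
  expect_identical(v$quantity, "rho_e")
  v0 <- electron_density_image(zeros, zeros, basis)
  expect_true(all(v0$values == 0))
  halves1 <- mk_volume(matrix(0.5, 16, 16))
  v5 <- electron_density_image(halves1, halves1, basis)
  expect_true(all(abs(v5$values - (basis$rho_e1 + basis$rho_e2) / 2)
                  < 1e-12))
  big <- mk_volume(matrix(0, 8, 8))
  expect_error(electron_density_image(ones, big, basis), "grids")
})

test_that("ROI means follow the voxel-center-inside rule", {
  v <- mk_volume(matrix(7, 21, 21))
  expect_equal(roi_mean(v, roi_spec(c(0, 0), 5)), 7)
  # single-voxel ROI picks that voxel
  v$values[11, 11] <- 42
  expect_equal(roi_mean(v, roi_spec(c(0, 0), 0.9)), 42)
  # checkerboard over an even ROI averages to 0.5
  v2 <- mk_volume(outer(1:20, 1:20, function(i, j) (i + j) %% 2))
  expect_equal(roi_mean(v2, roi_spec(c(0, 0), 4)), 0.5)
  expect_error(roi_mean(v, roi_spec(c(10, 0), 5)), "outside")
})

test_that("beam-hardening metric reproduces direct arithmetic", {
  # build a volume whose ROI means are exactly prescribed
  base <- matrix(100, 81, 81)
  v <- mk_volume(base, quantity = "HU")
  rois <- default_bh_rois(radius = 40, size = 3)
  expect_equal(beam_hardening_metric(v, rois$center, rois$periphery), 0)

  set_patch <- function(m, cx, cy, val) {
    ix <- 41 + cx + (-2:2); iy <- 41 + cy + (-2:2)
    m[ix, iy] <- val
    m
  }
  m <- base
  for (p in rois$periphery) {
    m <- set_patch(m, p$center[1], p$center[2], 104.73)
  }
  v2 <- mk_volume(m, quantity = "HU")
  expect_equal(beam_hardening_metric(v2, rois$center, rois$periphery),
               4.73, tolerance = 1e-12)
  # opposite deviations cancel in the peripheral mean
  m3 <- base
  vals <- c(96, 104, 96, 104)
  for (i in seq_along(rois$periphery)) {
    p <- rois$periphery[[i]]
    m3 <- set_patch(m3, p$center[1], p$center[2], vals[i])
  }
  v3 <- mk_volume(m3, quantity = "HU")
  expect_equal(beam_hardening_metric(v3, rois$center, rois$periphery), 0,
               tolerance = 1e-12)
  # near-zero center mean is an error, and exactly 4 peripheral ROIs
  vz <- mk_volume(matrix(0, 81, 81))
  expect_error(beam_hardening_metric(vz, rois$center, rois$periphery),
               "undefined")
  expect_error(beam_hardening_metric(v, rois$center, rois$periphery[1:3]),
               "four")
})

test_that("evaluation reports are self-consistent", {
  # synthetic rho_e volume holding the exact theoretical values
  ph <- build_virtual_phantom()
  n <- 161
  vals <- matrix(electron_density(get_material("water")), n, n)
  xs <- seq(-80, 80, by = 1)
  for (ins in ph$inserts) {
    ix <- which(abs(xs - ins$center[1]) <= ins$radius)
    iy <- which(abs(xs - ins$center[2]) <= ins$radius)
    vals[ix, iy] <- electron_density(ins$material)
  }
  v <- mk_volume(vals)
  rep <- evaluate_virtual_phantom(v, ph)
  expect_equal(nrow(rep), 5)
  expect_true(all(rep$error_pct == 0))
  expect_equal(attr(rep, "correlation"), 1.0)
  # spreadsheet-style recomputation from the report's own rows
  expect_equal(rep$error_pct,
               abs(rep$calculated - rep$theoretical) / rep$theoretical * 100)
  expect_equal(attr(rep, "correlation"),
               stats::cor(rep$calculated, rep$theoretical))
})
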