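test_that("virtual phantom has the documented layout and validation works", {
  ph <- build_virtual_phantom()
  expect_equal(ph$background$radius, 128)
  expect_length(ph$inserts, 4)
  expect_setequal(vapply(ph$inserts, function(i) i$material$name,
                         character(1)),
                  c("silicon", "pmma", "pe", "graphite"))
  # overlapping inserts and escaping inserts are rejected
  w <- get_material("water")
  expect_error(phantom_spec(
    background = list(material = w, center = c(0, 0), radius = 100),
    inserts = list(list(material = w, center = c(0, 0), radius = 30),
                   list(material = w, center = c(20, 0), radius = 30))),
    "overlap")
  expect_error(phantom_spec(
    background = list(material = w, center = c(0, 0), radius = 100),
    inserts = list(list(material = w, center = c(90, 0), radius = 30))),
    "inside")
})

test_that("scan geometry defaults and consistency checks", {
  g <- make_geometry(list())
  expect_equal(g$sdd / g$sad, 1.536)
  expect_equal(g$n_projections, 600L)
  expect_equal(g$angular_step, 0.6)
  expect_error(scan_geometry(n_projections = 601, angular_step = 0.6),
               "inconsistent")
  expect_error(scan_geometry(sad = 2000, sdd = 1536), "sad < sdd")
})

test_that("ray path lengths match analytic chords", {
  ph <- build_uniformity_phantom(100)  # water cylinder r = 50
  # central ray perpendicular to the axis: chord = diameter
  pl <- ray_path_lengths(ph, c(0, 1000, 0), c(0, -536, 0))
  expect_equal(unname(pl["water"]), 100, tolerance = 1e-10)
  # off-center ray at perpendicular distance h: chord = 2 sqrt(r^2 - h^2)
  h <- 30
  pl <- ray_path_lengths(ph, c(h, 1000, 0), c(h, -536, 0))
  expect_equal(unname(pl["water"]), 2 * sqrt(50^2 - h^2), tolerance = 1e-10)
  # miss
  pl <- ray_path_lengths(ph, c(60, 1000, 0), c(60, -536, 0))
  expect_equal(unname(pl["water"]), 0)
})

test_that("chords agree with a dense ray-sampling oracle", {
  ph <- build_virtual_phantom()
  geom <- small_fan_geom()
  beta <- 0.7
  od <- oracle_detector(geom, beta)
  for (k in c(20, 64, 100)) {
    pl <- ray_path_lengths(ph, c(od$src, 0), c(od$px[k], od$py[k], 0))
    # dense sampling of material indicator functions along the ray
    tseq <- seq(0, 1, length.out = 200001)
    xs <- od$src[1] + tseq * (od$px[k] - od$src[1])
    ys <- od$src[2] + tseq * (od$py[k] - od$src[2])
    dl <- sqrt((od$px[k] - od$src[1])^2 + (od$py[k] - od$src[2])^2) /
      (length(tseq) - 1)
    inside_bg <- xs^2 + ys^2 < ph$background$radius^2
    in_insert <- rep(FALSE, length(tseq))
    for (ins in ph$inserts) {
      hit <- (xs - ins$center[1])^2 + (ys - ins$center[2])^2 < ins$radius^2
      nm <- ins$material$name
      expect_lt(abs(unname(pl[nm]) - sum(hit) * dl), 0.05)
      in_insert <- in_insert | hit
    }
    expect_lt(abs(unname(pl["water"]) - sum(inside_bg & !in_insert) * dl),
              0.05)
  }
})

test_that("path lengths never exceed the background chord", {
  ph <- build_virtual_phantom()
  geom <- small_fan_geom()
  od <- oracle_detector(geom, 1.3)
  bg_chord <- oracle_chord(od$src, od$px, od$py, 0, 0,
                           ph$background$radius)
  for (k in seq(1, geom$det_cols, by = 7)) {
    pl <- ray_path_lengths(ph, c(od$src, 0), c(od$px[k], od$py[k], 0))
    expect_lte(sum(pl), bg_chord[k] + 1e-9)
    expect_true(all(pl >= 0))
  }
})

test_that("axial clipping bounds 3-D cone-beam chords", {
  # steep ray exits through the cylinder end face; chord is shorter than
  # the in-plane chord and bounded by height / |sin(angle to axis)|
  ph <- phantom_spec(background = list(material = get_material("water"),
                                       center = c(0, 0), radius = 50,
                                       height = 20))
  pl_flat <- ray_path_lengths(ph, c(0, 1000, 0), c(0, -536, 0))
  pl_steep <- ray_path_lengths(ph, c(0, 1000, 0), c(0, -536, 15))
  expect_equal(unname(pl_flat["water"]), 100)
  expect_lt(unname(pl_steep["water"]), 100)
  expect_gt(unname(pl_steep["water"]), 0)
})
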