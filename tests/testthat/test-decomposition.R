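test_that("LUT entries match an independent integration oracle", {
  bp <- basis_pair()
  sH <- generate_spectrum(120); sL <- generate_spectrum(70)
  d1g <- seq(0, 100, by = 10); d2g <- seq(0, 20, by = 2)
  lut <- build_lut(bp, sH, sL, d1g, d2g)
  expect_equal(lut$gH[1, 1], 0, tolerance = 1e-12)
  expect_equal(lut$gL[1, 1], 0, tolerance = 1e-12)
  # oracle: direct scalar quadrature of the two-slab transmitted intensity
  mu1H <- linear_attenuation(bp$material1, sH$energies)
  mu2H <- linear_attenuation(bp$material2, sH$energies)
  for (i in c(2, 6, 11)) {
    for (j in c(1, 5, 11)) {
      I <- sum(sH$weights * exp(-d1g[i] * mu1H - d2g[j] * mu2H))
      expect_equal(lut$gH[i, j], -log(I), tolerance = 1e-12)
    }
  }
  # strictly increasing along both thickness axes
  expect_true(all(apply(lut$gH, 1, diff) > 0))
  expect_true(all(apply(lut$gH, 2, diff) > 0))
  expect_true(all(apply(lut$gL, 1, diff) > 0))
  expect_true(all(apply(lut$gL, 2, diff) > 0))
})

test_that("monochromatic LUT reduces to the linear slab model", {
  bp <- basis_pair()
  lut <- build_lut(bp, delta_spectrum(80), delta_spectrum(50),
                   d1_grid = seq(0, 50, 10), d2_grid = seq(0, 10, 2))
  expect_equal(lut$gH[2, 1],
               linear_attenuation(bp$material1, 80) * 10,
               tolerance = 1e-12)
  # inversion equals the closed-form 2x2 linear solve
  M <- rbind(c(linear_attenuation(bp$material1, 80),
               linear_attenuation(bp$material2, 80)),
             c(linear_attenuation(bp$material1, 50),
               linear_attenuation(bp$material2, 50)))
  set.seed(11)
  d_true <- cbind(runif(20, 0, 50), runif(20, -2, 10))
  g <- d_true %*% t(M)
  sol <- invert_pair(lut, g[, 1], g[, 2])
  d_lin <- t(solve(M, t(g)))
  expect_equal(cbind(sol$d1, sol$d2), d_lin, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("round-trip inversion recovers thickness pairs to 0.01 mm", {
  lut <- memoize("lut_default", function() {
    build_lut(basis_pair(), generate_spectrum(120), generate_spectrum(70))
  })
  # lattice of off-grid points over the physical range
  d1 <- rep(seq(3.7, 397.7, length.out = 10), each = 10)
  d2 <- rep(seq(0.33, 59.33, length.out = 10), times = 10)
  fw <- lut_forward(lut, d1, d2)
  sol <- invert_pair(lut, fw$gH, fw$gL)
  expect_equal(attr(sol, "n_nonconverged"), 0)
  expect_lt(max(abs(sol$d1 - d1)), 0.01)
  expect_lt(max(abs(sol$d2 - d2)), 0.01)
  # forward of the solution reproduces g within the Newton tolerance
  chk <- lut_forward(lut, sol$d1, sol$d2)
  expect_lt(max(abs(chk$gH - fw$gH), abs(chk$gL - fw$gL)), 1e-6)
  # origin maps to origin
  s0 <- invert_pair(lut, 0, 0)
  expect_equal(c(s0$d1, s0$d2), c(0, 0), tolerance = 1e-9)
})

test_that("inversion is continuous in the measured projections", {
  lut <- memoize("lut_default", function() {
    build_lut(basis_pair(), generate_spectrum(120), generate_spectrum(70))
  })
  fw <- lut_forward(lut, 120, 15)
  base <- invert_pair(lut, fw$gH, fw$gL)
  eps <- 1e-4
  pert <- invert_pair(lut, fw$gH + eps, fw$gL - eps)
  # O(eps) bound with a generous conditioning constant
  expect_lt(abs(pert$d1 - base$d1) + abs(pert$d2 - base$d2), 1e3 * eps)
})

test_that("decomposing a pure-graphite object gives B2 ~ 0 and true chords", {
  lut <- memoize("lut_default", function() {
    build_lut(basis_pair(), generate_spectrum(120), generate_spectrum(70))
  })
  geom <- small_fan_geom(det_cols = 64, n_projections = 4)
  ph <- phantom_spec(background = list(material = get_material("graphite"),
                                       center = c(0, 0), radius = 30))
  pH <- polychromatic_projection(ph, geom, generate_spectrum(120))
  pL <- polychromatic_projection(ph, geom, generate_spectrum(70))
  bp <- decompose(pH, pL, lut)
  od <- oracle_detector(geom, 0)
  chord <- oracle_chord(od$src, od$px, od$py, 0, 0, 30)
  expect_lt(max(abs(bp$B2)), 0.1)
  expect_equal(as.vector(bp$B1[1, 1, ]), chord, tolerance = 1e-3)
  # zero projections decompose to zero without iteration
  p0 <- pH; p0$values[] <- 0
  b0 <- decompose(p0, p0, lut)
  expect_true(all(b0$B1 == 0) && all(b0$B2 == 0))
})

test_that("water decomposition conserves the electron-density line integral", {
  lut <- memoize("lut_default", function() {
    build_lut(basis_pair(), generate_spectrum(120), generate_spectrum(70))
  })
  geom <- small_fan_geom(det_cols = 64, n_projections = 2)
  ph <- build_uniformity_phantom(200)
  pH <- polychromatic_projection(ph, geom, generate_spectrum(120))
  pL <- polychromatic_projection(ph, geom, generate_spectrum(70))
  bp <- decompose(pH, pL, lut)
  basis <- basis_pair()
  rho_w <- electron_density(get_material("water"))
  od <- oracle_detector(geom, 0)
  chord <- oracle_chord(od$src, od$px, od$py, 0, 0, 100)
  inside <- chord > 20
  de_line <- bp$B1[1, 1, ] * basis$rho_e1 + bp$B2[1, 1, ] * basis$rho_e2
  expect_equal(de_line[inside], rho_w * chord[inside], tolerance = 0.01)
  expect_true(all(bp$B2[1, 1, inside] != 0))
})

test_that("geometry mismatches are rejected", {
  lut <- memoize("lut_default", function() {
    build_lut(basis_pair(), generate_spectrum(120), generate_spectrum(70))
  })
  geom <- small_fan_geom(det_cols = 16, n_projections = 2)
  ph <- build_uniformity_phantom(100)
  pH <- polychromatic_projection(ph, geom, generate_spectrum(120))
  pL <- polychromatic_projection(ph, small_fan_geom(det_cols = 32,
                                                    n_projections = 2),
                                 generate_spectrum(70))
  expect_error(decompose(pH, pL, lut), "mismatch")
})
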