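test_that("water delta matches the electron-density closed form", {
  # independent oracle: delta = r_e lambda^2 n_e / (2 pi) for water
  r_e <- 2.8179403262e-13            # cm
  lambda <- 12.398419843 / 17 * 1e-8 # cm
  n_e <- 1.0 * 6.02214076e23 * (2 * 1 + 8) / 18.015  # electrons per cm^3
  delta_oracle <- r_e * lambda^2 * n_e / (2 * pi)
  m <- optical_constants("water", 17)
  expect_lt(abs(m$delta - delta_oracle) / delta_oracle, 0.02)
})

test_that("gas core uses vacuum optical constants", {
  m <- optical_constants("gas_core", 17)
  expect_identical(m$delta, 0)
  expect_identical(m$mu, 0)
})

test_that("nylon-12 wall is a low-contrast match to the water lumen", {
  # the wall is chosen for low contrast against water; its attenuation is
  # the same order of magnitude (ratio ~0.6 at 17 keV for PA12 at 1.01 g/cc)
  mw <- optical_constants("water", 17)
  mn <- optical_constants("nylon12", 17)
  expect_gt(mn$mu / mw$mu, 0.4)
  expect_lt(mn$mu / mw$mu, 1.1)
  # and nearly matched refractive-index decrement (phase contrast is weak)
  expect_lt(abs(mn$delta - mw$delta) / mw$delta, 0.1)
})

test_that("unknown materials and out-of-range energies are rejected", {
  expect_error(optical_constants("lead", 17), "supported materials")
  expect_error(optical_constants("water", 40), "outside tabulated range")
})

test_that("optical constants interpolate smoothly and decrease with energy", {
  e <- seq(15, 20, by = 0.25)
  d <- vapply(e, function(x) optical_constants("water", x)$delta, numeric(1))
  mu <- vapply(e, function(x) optical_constants("water", x)$mu, numeric(1))
  expect_true(all(diff(d) < 0))
  expect_true(all(diff(mu) < 0))
  # tabulated points are reproduced exactly
  tab17 <- optical_constants("water", 17)
  expect_equal(tab17$delta, 7.983721e-07, tolerance = 1e-6)
})

test_that("reflectivity has the defining Gaussian landmarks", {
  rc <- rocking_curve(fwhm_urad = 20, peak_reflectivity = 0.9)
  expect_equal(reflectivity(rc, 0), 0.9)
  expect_equal(reflectivity(rc, 10), 0.45)   # FWHM/2 -> half peak
  expect_equal(reflectivity(rc, -10), 0.45)  # symmetry
  sigma <- 20 / (2 * sqrt(2 * log(2)))
  expect_equal(reflectivity(rc, sigma * sqrt(2 * log(20))), 0.05 * 0.9,
               tolerance = 1e-12)
})

test_that("working point honours the requested reflectivity level", {
  # analytic: offset = sigma * sqrt(2 ln 20) = 2.4478 sigma for 5%
  sigma10 <- rocking_curve(fwhm_urad = 10 * 2 * sqrt(2 * log(2)))
  wp <- find_working_point(sigma10, 0.05)
  expect_equal(wp$offset_urad, 10 * sqrt(2 * log(20)), tolerance = 1e-9)
  expect_equal(wp$offset_urad, 24.478, tolerance = 1e-4)
  rc <- rocking_curve(fwhm_urad = 20)
  expect_equal(find_working_point(rc, 0.5)$offset_urad, 10,
               tolerance = 1e-9)
  expect_error(find_working_point(rc, 1.0), "strictly between")
  expect_error(find_working_point(rc, 0), "strictly between")
  neg <- find_working_point(rc, 0.05, side = "negative")
  expect_lt(neg$offset_urad, 0)
})

test_that("working-point round trip holds for both profile families", {
  for (shape in c("gaussian", "pseudo_voigt")) {
    rc <- rocking_curve(shape, fwhm_urad = 17, peak_reflectivity = 0.8)
    for (L in c(0.01, 0.05, 0.5)) {
      wp <- find_working_point(rc, L)
      expect_equal(reflectivity(rc, wp$offset_urad),
                   L * rc$peak_reflectivity, tolerance = 1e-6)
    }
  }
})

test_that("reflectivity decreases monotonically with |deviation|", {
  for (shape in c("gaussian", "pseudo_voigt")) {
    rc <- rocking_curve(shape, fwhm_urad = 20)
    dev <- seq(0, 200, by = 0.05)
    r <- reflectivity(rc, dev)
    expect_true(all(diff(r) < 0))
    expect_true(all(r >= 0 & r <= rc$peak_reflectivity))
    expect_equal(reflectivity(rc, -dev), r)
  }
})
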