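test_that("closed-form sphere deflection behaves as the ray-optics formula", {
  expect_equal(sphere_deflection_closed_form(8e-7, 4, 0), 0)
  # b/sqrt(r^2-b^2) = 1 at b = r/sqrt(2)
  expect_equal(sphere_deflection_closed_form(8e-7, 4, 4 / sqrt(2)), 1.6,
               tolerance = 1e-12)
  b <- seq(0, 0.95 * 4, length.out = 50)
  d <- sphere_deflection_closed_form(8e-7, 4, b)
  expect_true(all(diff(d) > 0))
  expect_error(sphere_deflection_closed_form(8e-7, 4, 4), "impact")
})

test_that("numerical tracer matches the single-sphere analytic oracle", {
  # 200 random (energy, r, b, position) cases; the sphere contribution is
  # isolated by subtracting the bubble-free trace of the same ray
  grid <- small_grid()
  g <- small_geometry(grid)
  ph0 <- generate_phantom(g, size_distribution(), 0, seed = 1)
  set.seed(20)
  n_bad <- 0L
  for (k in 1:200) {
    e <- runif(1, 15, 20)
    mat <- phantom_materials(e)
    r_um <- runif(1, 2, 15)
    frac <- runif(1, 0.05, 0.9)
    b_um <- frac * r_um
    cx <- runif(1, 0.3, g$length_mm - 0.3)
    cy <- runif(1, -1, 1)
    phi <- runif(1, 0, 2 * pi)  # orientation of the impact offset
    ph1 <- ph0
    ph1$spheres <- data.frame(x = cx, y = cy, z = 0, r = r_um * 1e-3)
    rx <- cx + b_um * 1e-3 * cos(phi)
    ry <- cy + b_um * 1e-3 * sin(phi)
    with_sphere <- trace_ray(list(x_mm = rx, y_mm = ry), ph1, mat)
    without <- trace_ray(list(x_mm = rx, y_mm = ry), ph0, mat)
    got <- with_sphere$deflection_urad - without$deflection_urad
    # only the diffraction-plane (y) component is sensed
    want <- -sphere_deflection_closed_form(mat$lumen$delta, r_um, b_um) *
      sin(phi)
    denom <- sphere_deflection_closed_form(mat$lumen$delta, r_um, b_um)
    if (abs(got - want) / denom > 0.01) n_bad <- n_bad + 1L
  }
  expect_identical(n_bad, 0L)
})

test_that("attenuation bookkeeping: bubble-free chords and gas chords", {
  grid <- small_grid()
  g <- small_geometry(grid)
  mat <- phantom_materials(17)
  ph0 <- generate_phantom(g, size_distribution(), 0, seed = 1)
  # central ray: water chord = ID, wall chord = 2 * wall thickness
  ray <- trace_ray(list(x_mm = g$length_mm / 2, y_mm = 0), ph0, mat)
  expect_equal(ray$weight, exp(-mat$lumen$mu * 4 - mat$wall$mu * 2),
               tolerance = 1e-12)
  expect_equal(ray$deflection_urad, 0)
  # ray missing the tube entirely is unchanged
  miss <- trace_ray(list(x_mm = 1, y_mm = 10), ph0, mat)
  expect_equal(miss$weight, 1)
  expect_equal(miss$deflection_urad, 0)
  # a central chord through a sphere replaces water with gas
  ph1 <- ph0
  ph1$spheres <- data.frame(x = 0.5, y = 0, z = 0, r = 10e-3)
  through <- trace_ray(list(x_mm = 0.5, y_mm = 0), ph1, mat)
  expect_equal(through$weight,
               exp(-mat$lumen$mu * (4 - 0.02) - mat$wall$mu * 2),
               tolerance = 1e-12)
  expect_equal(through$deflection_urad, 0)  # normal incidence
})

test_that("energy bookkeeping: unit reflectivity and no absorption keep flux", {
  grid <- small_grid(rays_per_pixel = 4L)
  g <- small_geometry(grid)
  ph <- generate_phantom(g, size_distribution(), 0.003, seed = 5)
  flat <- rocking_curve(fwhm_urad = 1e9)  # constant ~1 over all deviations
  wp0 <- structure(list(offset_urad = 0, level = 1, side = "positive"),
                   class = "working_point")
  vac <- list(lumen = list(delta = 8e-7, mu = 0),
              wall = list(delta = 9e-7, mu = 0),
              gas = list(delta = 0, mu = 0),
              ambient = list(delta = 0, mu = 0))
  f <- render_frame(ph, grid, flat, wp0, vac, noise = FALSE, seed = 2)
  expect_equal(as.vector(f), rep(1, length(f)), tolerance = 1e-9)
})

test_that("flat field with no sample sits at the working-point reflectivity", {
  grid <- small_grid(rays_per_pixel = 2L)
  f <- render_frame(NULL, grid, std_curve, std_wp, std_materials,
                    noise = FALSE, seed = 1)
  expect_equal(as.vector(f), rep(0.05, length(f)), tolerance = 1e-12)
  expect_true(all(f >= 0))
})

test_that("dark-field signal grows with microbubble concentration", {
  grid <- small_grid()
  g <- small_geometry(grid)
  roi <- roi_rect(grid, g)
  conc <- c(0, 0.0025, 0.005, 0.0075, 0.01)
  for (seed in 1:3) {
    means <- vapply(seq_along(conc), function(i) {
      ph <- generate_phantom(g, size_distribution(), conc[i],
                             seed = 100 * seed + i)
      frame_roi_mean(render_frame(ph, grid, std_curve, std_wp,
                                  std_materials, noise = FALSE,
                                  seed = 7), roi)
    }, numeric(1))
    expect_true(all(diff(means) > 0))
  }
})

test_that("Poisson noise has variance ~ mean on a flat field", {
  grid <- detector_grid(n_rows = 128L, n_cols = 80L, rays_per_pixel = 1L,
                        photons_per_pixel = 1e4)
  f <- render_frame(NULL, grid, std_curve, std_wp, std_materials,
                    noise = TRUE, seed = 42)
  counts <- as.vector(f) * 1e4
  expect_equal(var(counts) / mean(counts), 1, tolerance = 0.05)
})

test_that("rendering is deterministic under a fixed seed", {
  grid <- small_grid(rays_per_pixel = 8L)
  g <- small_geometry(grid)
  ph <- generate_phantom(g, size_distribution(), 0.004, seed = 3)
  f1 <- render_frame(ph, grid, std_curve, std_wp, std_materials,
                     noise = TRUE, seed = 99)
  f2 <- render_frame(ph, grid, std_curve, std_wp, std_materials,
                     noise = TRUE, seed = 99)
  expect_identical(as.vector(f1), as.vector(f2))
})

test_that("sequences decay in concentration and support degenerate cases", {
  grid <- small_grid(rays_per_pixel = 8L)
  g <- small_geometry(grid)
  tm <- acquisition_timing()
  one <- render_sequence(g, size_distribution(),
                         dilution_model(C1 = 0.005, D = 0.1), tm, 1L,
                         grid, std_curve, std_wp, std_materials,
                         noise = FALSE, seed = 2)
  expect_length(one$frames, 1L)
  expect_equal(one$times_s, 0.25)

  # D = 0: all frames are fresh draws at the same concentration
  roi <- roi_rect(grid, g)
  const <- render_sequence(g, size_distribution(),
                           dilution_model(C1 = 0.005, D = 0), tm, 6L,
                           grid, std_curve, std_wp, std_materials,
                           noise = FALSE, seed = 8)
  m <- roi_mean_series(const, roi)$mean
  expect_lt(diff(range(m)) / mean(m), 0.05)  # within Monte Carlo scatter
  expect_equal(const$concentration, rep(0.005, 6))
})

test_that("image sequences round-trip through TIFF + sidecar CSV", {
  grid <- small_grid(rays_per_pixel = 4L)
  g <- small_geometry(grid)
  sq <- render_sequence(g, size_distribution(),
                        dilution_model(C1 = 0.004, D = 0.2),
                        acquisition_timing(), 3L, grid, std_curve, std_wp,
                        std_materials, noise = TRUE, seed = 5)
  tp <- withr::local_tempfile(fileext = ".tiff")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_sequence(sq, tp, cp)
  back <- read_sequence(tp, cp)
  expect_length(back$frames, 3L)
  expect_equal(back$times_s, sq$times_s)
  expect_equal(back$concentration, sq$concentration, tolerance = 1e-12)
  for (k in 1:3) {
    expect_equal(as.vector(back$frames[[k]]), as.vector(sq$frames[[k]]),
                 tolerance = 1e-6)  # float32 storage
  }
})
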