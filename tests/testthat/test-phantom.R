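test_that("radius sampling respects the distribution contract", {
  d <- size_distribution()
  expect_identical(sample_radii(d, 0), numeric(0))
  r <- sample_radii(d, 1e5, seed = 4)
  expect_true(all(r >= d$min_radius_um & r <= d$max_radius_um))
  # large-sample median consistency oracle
  expect_lt(abs(median(r) - 4) / 4, 0.05)
  # determinism
  expect_identical(r, sample_radii(d, 1e5, seed = 4))
  # zero-spread limit
  mono <- size_distribution(geometric_sd = 1)
  expect_equal(sample_radii(mono, 50), rep(4, 50))
  expect_error(size_distribution(min_radius_um = 5, max_radius_um = 2),
               "truncation")
})

test_that("lumen volume is the cylinder formula", {
  g <- vessel_geometry(inner_diameter_mm = 4, length_mm = 1)
  expect_equal(lumen_volume(g), 4 * pi)
  g2 <- vessel_geometry(inner_diameter_mm = 4, length_mm = 2)
  expect_equal(lumen_volume(g2), 2 * lumen_volume(g))
  expect_error(vessel_geometry(inner_diameter_mm = 0))
})

test_that("phantom generation meets concentration, overlap and determinism contracts", {
  g <- vessel_geometry(length_mm = 0.15)
  d <- size_distribution()

  empty <- generate_phantom(g, d, 0, seed = 1)
  expect_identical(nrow(empty$spheres), 0L)
  expect_identical(empty$realized_concentration, 0)

  ph <- generate_phantom(g, d, 0.001, seed = 7)
  # direct summation oracle for the realized volume fraction
  vol <- sum(4 / 3 * pi * ph$spheres$r^3) / lumen_volume(g)
  expect_equal(ph$realized_concentration, vol)
  expect_lt(abs(vol - 0.001) / 0.001, 0.02)
  # spheres entirely inside the lumen
  expect_true(all(sqrt(ph$spheres$y^2 + ph$spheres$z^2) + ph$spheres$r <=
                    g$inner_diameter_mm / 2 + 1e-12))
  expect_true(all(ph$spheres$x >= 0 & ph$spheres$x <= g$length_mm))
  # brute-force all-pairs overlap check
  expect_lt(nrow(ph$spheres), 5000)
  expect_identical(count_overlaps(ph), 0L)
  # byte-identical under the same seed
  ph2 <- generate_phantom(g, d, 0.001, seed = 7)
  expect_identical(ph$spheres, ph2$spheres)

  expect_error(generate_phantom(g, d, 0.2, seed = 1), "packing limit")
  expect_error(generate_phantom(g, d, -0.1, seed = 1), "nonnegative")
})

test_that("sphere centres are spatially uniform across lumen octants", {
  g <- vessel_geometry(length_mm = 0.6)
  d <- size_distribution()
  for (seed in 1:20) {
    ph <- generate_phantom(g, d, 0.002, seed = seed)
    sp <- ph$spheres
    oct <- 4 * (sp$x > g$length_mm / 2) + 2 * (sp$y > 0) + (sp$z > 0)
    counts <- table(factor(oct, levels = 0:7))
    p <- suppressWarnings(chisq.test(as.vector(counts))$p.value)
    expect_gt(p, 0.001)
  }
})

test_that("realized sphere count grows with target concentration", {
  g <- vessel_geometry(length_mm = 0.3)
  d <- size_distribution()
  n <- vapply(c(0.0005, 0.001, 0.002, 0.004),
              function(cc) nrow(generate_phantom(g, d, cc, seed = 3)$spheres),
              numeric(1))
  expect_true(all(diff(n) > 0))
})

test_that("phantom CSV serialization round-trips", {
  g <- vessel_geometry(length_mm = 0.15)
  ph <- generate_phantom(g, size_distribution(), 0.0008, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_phantom_csv(ph, path)
  back <- read_phantom_csv(path)
  expect_equal(back$spheres, ph$spheres, tolerance = 1e-12)
  expect_equal(back$geometry, ph$geometry)
  expect_equal(back$realized_concentration, ph$realized_concentration)
  expect_identical(back$seed, 9L)
})
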