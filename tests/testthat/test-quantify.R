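# one shared calibration benchmark for the quantification tests (noise on,
# reduced resolution)
quant_grid <- small_grid()
quant_geom <- small_geometry(quant_grid)
quant_roi <- roi_rect(quant_grid, quant_geom)
quant_cal <- fit_linear(build_calibration(
  c(0, 0.0025, 0.005, 0.0075, 0.01), quant_geom, size_distribution(),
  quant_grid, std_curve, std_wp, std_materials, noise = TRUE, n_reps = 3,
  seed = 314))

test_that("ROI extraction averages exactly and validates bounds", {
  f <- structure(matrix(2.5, 96, 32), class = c("image_frame", "matrix"))
  expect_equal(frame_roi_mean(f, quant_roi), 2.5)
  big_roi <- quant_roi
  big_roi$rows <- c(1L, 500L)
  expect_error(frame_roi_mean(f, big_roi), "outside the image")
  # ROI excludes wall pixels by construction
  p_mm <- quant_grid$pixel_eff_um * 1e-3
  row_y <- (quant_grid$n_rows / 2 - seq_len(quant_grid$n_rows) + 0.5) * p_mm
  expect_true(all(abs(row_y[quant_roi$rows[1]:quant_roi$rows[2]]) <= 1))
})

test_that("background subtraction maps zero concentration to ~zero", {
  s <- make_series(c(1, 2, 3), c(5, 5, 5))
  expect_equal(subtract_background(s, 5)$mean, c(0, 0, 0))
  expect_equal(subtract_background(s, 0)$mean, s$mean)
  # bubble-free frames after subtraction sit within 3 sigma_MC of zero
  bg <- background_roi_stats(quant_geom, quant_grid, std_curve, std_wp,
                             quant_roi, std_materials, noise = TRUE,
                             n_reps = 6, seed = 77)
  resid <- bg$means - quant_cal$background
  expect_true(all(abs(resid) <= 3 * (bg$sd + quant_cal$sigma)))
})

test_that("calibration requires >= 3 levels including zero, then increases", {
  d <- size_distribution()
  expect_error(build_calibration(c(0, 0.005), quant_geom, d, quant_grid,
                                 std_curve, std_wp),
               "3 distinct")
  expect_error(build_calibration(c(0.002, 0.005, 0.01), quant_geom, d,
                                 quant_grid, std_curve, std_wp),
               "zero-concentration")
  expect_true(all(diff(quant_cal$data$mean_sub) > 0))
  expect_equal(quant_cal$data$mean_sub[1], 0)  # self-subtraction at c = 0
})

test_that("linear fit returns OLS diagnostics and rejects degenerate input", {
  # exactly collinear synthetic points -> zero residuals
  fake <- structure(list(
    data = data.frame(concentration = c(0, 0.002, 0.004, 0.008),
                      mean_raw = 1 + 3 * c(0, 0.002, 0.004, 0.008),
                      mean_sub = 3 * c(0, 0.002, 0.004, 0.008),
                      se = rep(0, 4)),
    background = 1, sigma = 1e-5, n_reps = 1, roi = NULL, fit = NULL),
    class = "calibration_curve")
  ft <- suppressWarnings(fit_linear(fake))  # exact fit: R^2 warning only
  expect_equal(ft$fit$slope, 3)
  expect_equal(ft$fit$intercept, 0, tolerance = 1e-12)
  expect_equal(ft$fit$residuals, rep(0, 4), tolerance = 1e-12)
  expect_equal(ft$fit$r_squared, 1)

  degen <- fake
  degen$data <- data.frame(concentration = c(0.005, 0.005, 0.005),
                           mean_raw = c(1, 2, 3), mean_sub = c(1, 2, 3),
                           se = 0)
  expect_error(fit_linear(degen), "single distinct")

  # the simulated benchmark is approximately linear with high R^2
  expect_gt(quant_cal$fit$r_squared, 0.95)
})

test_that("concentration estimation inverts the calibration line", {
  expect_error(estimate_concentration(0.01, build_calibration(
    c(0, 0.0025, 0.005), quant_geom, size_distribution(), quant_grid,
    std_curve, std_wp, noise = FALSE, n_reps = 1, seed = 2)),
    "fit_linear")
  # intensity exactly on the line round-trips
  on_line <- quant_cal$fit$intercept + quant_cal$fit$slope * 0.005
  expect_equal(estimate_concentration(on_line, quant_cal), 0.005,
               tolerance = 1e-12)
  # intensity 0 clips to ~0 (exactly 0 when the intercept is positive)
  expect_gte(estimate_concentration(0, quant_cal), 0)
  expect_lt(estimate_concentration(0, quant_cal), 5e-4)
  expect_warning(estimate_concentration(10, quant_cal), "extrapolat")
  # round-trip through forward simulation within 10% at calibrated levels
  lv <- quant_cal$data$concentration[-1]
  est <- estimate_concentration(quant_cal$data$mean_sub[-1], quant_cal)
  expect_true(all(abs(est - lv) / lv <= 0.10))
})

test_that("decay-constant fit inverts a noiseless exponential exactly", {
  tm <- frame_times(acquisition_timing(), 30)
  s <- make_series(tm, 0.027 + 0.012 * exp(-0.056 * tm))
  est <- estimate_decay_constant(s, background = 0.027, sigma_bg = 0,
                                 n_boot = 50, seed = 1)
  expect_equal(est$D_hat, 0.056, tolerance = 1e-10)
  expect_identical(est$n_used, 30L)
  # errors on a series with nothing above background
  flat <- make_series(tm, rep(0.027, 30))
  expect_error(estimate_decay_constant(flat, 0.027, sigma_bg = 1e-5),
               "no signal above background")
  expect_error(estimate_decay_constant(make_series(1:5, 6:10), 0),
               "at least 8 frames")
  # too-shallow decay is refused rather than poorly fitted
  shallow <- make_series(tm, 0.027 + 0.012 * exp(-0.005 * tm))
  expect_error(estimate_decay_constant(shallow, 0.027, sigma_bg = 0),
               "e-folding")
  # bootstrap CI brackets the estimate and is seeded
  est2 <- estimate_decay_constant(s, 0.027, sigma_bg = 0, n_boot = 50,
                                  seed = 1)
  expect_identical(est$ci, est2$ci)
  expect_true(est$ci[1] <= est$D_hat && est$D_hat <= est$ci[2])
})

test_that("Rose-criterion detection limit scales with noise and slope", {
  lim <- detection_limit(quant_cal, 5)
  expect_gt(lim, 0)
  expect_lt(lim, 0.01)
  noisier <- quant_cal
  noisier$sigma <- 2 * quant_cal$sigma
  expect_equal(detection_limit(noisier, 5), 2 * lim)
  noiseless <- quant_cal
  noiseless$sigma <- 0
  expect_equal(detection_limit(noiseless, 5), 0)
  flat <- quant_cal
  flat$fit$slope <- 0
  expect_error(detection_limit(flat, 5), "slope")
})

test_that("series alignment puts the common intensity level at t = 0", {
  t <- seq(0, 20, by = 0.77)
  s1 <- make_series(t, 0.02 + 0.01 * exp(-0.1 * t))
  s2 <- make_series(t, 0.02 + 0.02 * exp(-0.1 * t))
  al <- align_at_intensity(list(s1, s2), level = 0.025)
  for (s in al) {
    # interpolated crossing of the level sits at time zero
    i <- which(s$mean <= 0.025)[1]
    expect_true(s$time_s[i - 1] < 0 && s$time_s[i] >= 0)
  }
})
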