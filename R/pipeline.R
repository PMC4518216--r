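#' Instantiate simulation objects from a configuration
#'
#' Pure plumbing: turns the configuration sections into the package's
#' domain objects. The phantom segment length is set to the detector field
#' of view along the vessel axis.
#'
#' @param config a [default_config()]-shaped list.
#' @return list with \code{materials}, \code{curve}, \code{wp},
#'   \code{geometry}, \code{dist}, \code{grid}, \code{timing},
#'   \code{dilution}, \code{roi}.
#' @export
build_setup <- function(config) {
  grid <- detector_grid(config$detector$pixel_um, config$detector$binning,
                        config$detector$n_rows, config$detector$n_cols,
                        config$detector$rays_per_pixel,
                        config$detector$photons_per_pixel)
  geometry <- vessel_geometry(
    config$geometry$inner_diameter_mm, config$geometry$wall_thickness_mm,
    length_mm = field_of_view(grid)[["width_mm"]])
  curve <- rocking_curve(config$rocking_curve$shape,
                         config$rocking_curve$fwhm_urad,
                         config$rocking_curve$peak_reflectivity,
                         config$rocking_curve$eta)
  wp <- find_working_point(curve, config$rocking_curve$working_level,
                           config$rocking_curve$side)
  dist <- size_distribution(median_radius_um = config$bubbles$median_radius_um,
                            geometric_sd = config$bubbles$geometric_sd,
                            min_radius_um = config$bubbles$min_radius_um,
                            max_radius_um = config$bubbles$max_radius_um)
  dilution <- dilution_model(C1 = config$dilution$C1, D = config$dilution$D,
                             Q = config$dilution$Q, V_p = config$dilution$V_p,
                             V_l = config$dilution$V_l, R = config$dilution$R)
  list(materials = phantom_materials(config$beam$energy_kev),
       curve = curve, wp = wp, geometry = geometry, dist = dist,
       grid = grid, timing = acquisition_timing(config$timing$exposure_s,
                                                config$timing$readout_s),
       dilution = dilution,
       roi = roi_rect(grid, geometry, config$quantify$roi_lumen_fraction))
}

config_echo_path <- function(outdir) file.path(outdir, "config_echo.yaml")

write_config_echo <- function(config, outdir) {
  echo <- config
  echo$config_hash <- config_hash(yaml::as.yaml(config))
  save_config(echo, config_echo_path(outdir))
  echo$config_hash
}

#' Simulate a decaying-concentration image sequence and write it to disk
#'
#' @param config configuration list (see [default_config()]).
#' @param outdir output directory (created if missing).
#' @param seed overrides \code{config$seed} when given.
#' @return list with the \code{image_sequence} and the written paths,
#'   invisibly.
#' @export
run_simulate <- function(config = default_config(),
                         outdir = "mbxpci_out", seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  s <- build_setup(config)
  seq <- render_sequence(s$geometry, s$dist, s$dilution, s$timing,
                         config$sequence$n_frames, s$grid, s$curve, s$wp,
                         s$materials, noise = config$detector$noise,
                         seed = config$seed)
  paths <- write_sequence(seq, file.path(outdir, "sequence.tiff"),
                          file.path(outdir, "frame_table.csv"))
  hash <- write_config_echo(config, outdir)
  message("sequence: ", length(seq$frames), " frames written to ", outdir,
          " (config ", hash, ")")
  invisible(list(sequence = seq, paths = paths, config_hash = hash))
}

#' Build, fit and write the intensity-concentration calibration
#'
#' @inheritParams run_simulate
#' @return list with the fitted \code{calibration_curve}, the Rose-criterion
#'   detection limit and the written path, invisibly.
#' @export
run_calibrate <- function(config = default_config(),
                          outdir = "mbxpci_out", seed = NULL) {
  validate_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  s <- build_setup(config)
  cal <- build_calibration(config$quantify$calibration_levels, s$geometry,
                           s$dist, s$grid, s$curve, s$wp, s$materials,
                           noise = config$detector$noise,
                           n_reps = config$quantify$n_reps,
                           seed = config$seed)
  cal <- fit_linear(cal)
  limit <- detection_limit(cal, config$quantify$snr_threshold)
  path <- file.path(outdir, "calibration.csv")
  out <- cal$data
  out$residual <- cal$fit$residuals
  utils::write.csv(out, path, row.names = FALSE)
  hash <- write_config_echo(config, outdir)
  message(sprintf(
    "calibration: slope %.4g, intercept %.3g, R^2 %.4f, detection limit %.3g (config %s)",
    cal$fit$slope, cal$fit$intercept, cal$fit$r_squared, limit, hash))
  invisible(list(calibration = cal, detection_limit = limit, path = path,
                 config_hash = hash))
}

#' Quantify a sequence against a calibration
#'
#' Extracts the ROI series, subtracts the background, converts intensity to
#' concentration through the fitted calibration, and recovers the decay
#' constant by the log-linear fit with bootstrap confidence interval.
#'
#' @param sequence an \code{image_sequence} (e.g. from [run_simulate()] or
#'   [read_sequence()]).
#' @param calibration a fitted \code{calibration_curve} (from
#'   [run_calibrate()]); supplies the background intensity and noise level.
#' @inheritParams run_simulate
#' @return list with the intensity/concentration series (data.frame) and
#'   the decay-constant report, invisibly.
#' @export
run_quantify <- function(sequence, calibration,
                         config = default_config(),
                         outdir = "mbxpci_out") {
  validate_config(config)
  if (is.null(calibration$fit)) {
    stop("calibration must be fitted (run_calibrate does this)")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  s <- build_setup(config)
  series <- roi_mean_series(sequence, s$roi)
  sub <- subtract_background(series, calibration$background)
  est <- estimate_decay_constant(series, calibration$background,
                                 sigma_bg = calibration$sigma,
                                 noise_floor_mult = config$quantify$noise_floor_mult,
                                 n_boot = config$quantify$n_boot,
                                 seed = config$seed)
  conc_hat <- suppressWarnings(
    estimate_concentration(sub$mean, calibration))
  out <- data.frame(time_s = series$time_s, roi_mean = series$mean,
                    roi_mean_sub = sub$mean, concentration_hat = conc_hat)
  if (!is.null(series$concentration_true)) {
    out$concentration_true <- series$concentration_true
  }
  utils::write.csv(out, file.path(outdir, "series.csv"), row.names = FALSE)
  report <- list(
    D_hat_per_s = est$D_hat,
    D_ci = as.numeric(est$ci),
    n_frames_used = est$n_used,
    background = calibration$background,
    sigma = calibration$sigma,
    config_hash = write_config_echo(config, outdir)
  )
  yaml::write_yaml(report, file.path(outdir, "report.yaml"))
  message(sprintf("decay constant: D_hat = %.4g 1/s (CI %.4g..%.4g, %d frames)",
                  est$D_hat, est$ci[1], est$ci[2], est$n_used))
  invisible(list(series = out, decay = est, report = report))
}

#' Full pipeline: simulate, calibrate, quantify
#'
#' @inheritParams run_simulate
#' @return list with all intermediate results, invisibly.
#' @export
run_all <- function(config = default_config(), outdir = "mbxpci_out",
                    seed = NULL) {
  sim <- run_simulate(config, outdir, seed)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  cal <- run_calibrate(config, outdir)
  qnt <- run_quantify(sim$sequence, cal$calibration, config, outdir)
  invisible(list(sequence = sim$sequence, calibration = cal$calibration,
                 detection_limit = cal$detection_limit,
                 quantification = qnt))
}
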