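#' Rectangular analysis ROI in the tube lumen
#'
#' The analysis region is a band centred on the vessel axis covering a
#' fraction of the lumen width (default the central 50\%), over all image
#' columns. Wall pixels and the strongly refracting lumen edges are always
#' excluded by construction.
#'
#' @param grid a [detector_grid()].
#' @param geometry a [vessel_geometry()].
#' @param lumen_fraction fraction of the lumen diameter covered, in (0, 1).
#' @return object of class \code{roi}: list with inclusive 1-based
#'   \code{rows = c(first, last)} and \code{cols = c(first, last)}.
#' @export
roi_rect <- function(grid, geometry, lumen_fraction = 0.5) {
  stopifnot(inherits(grid, "detector_grid"),
            inherits(geometry, "vessel_geometry"),
            lumen_fraction > 0, lumen_fraction < 1)
  p_mm <- grid$pixel_eff_um * 1e-3
  half <- lumen_fraction * geometry$inner_diameter_mm / 2
  row_y <- (grid$n_rows / 2 - seq_len(grid$n_rows) + 0.5) * p_mm
  inside <- which(abs(row_y) <= half)
  if (!length(inside)) stop("ROI empty: lumen band narrower than one pixel")
  structure(list(rows = range(inside), cols = c(1L, grid$n_cols),
                 lumen_fraction = lumen_fraction),
            class = "roi")
}

roi_pixels <- function(frame, roi) {
  if (roi$rows[1] < 1 || roi$rows[2] > nrow(frame) ||
      roi$cols[1] < 1 || roi$cols[2] > ncol(frame)) {
    stop("ROI extends outside the image (", nrow(frame), " x ",
         ncol(frame), " pixels)")
  }
  unclass(frame)[roi$rows[1]:roi$rows[2], roi$cols[1]:roi$cols[2]]
}

#' Mean ROI intensity of one frame
#'
#' @param frame an \code{image_frame} (or plain matrix).
#' @param roi a [roi_rect()] result.
#' @return scalar mean intensity over the ROI.
#' @export
frame_roi_mean <- function(frame, roi) {
  mean(roi_pixels(frame, roi))
}

#' ROI mean-intensity time series of a sequence
#'
#' @param seq an \code{image_sequence}.
#' @param roi a [roi_rect()] result.
#' @return an \code{intensity_series}: data.frame with \code{time_s} and
#'   \code{mean}, one row per frame, plus the true concentration where the
#'   sequence carries it.
#' @export
roi_mean_series <- function(seq, roi) {
  stopifnot(inherits(seq, "image_sequence"))
  means <- vapply(seq$frames, frame_roi_mean, numeric(1), roi = roi)
  out <- data.frame(time_s = seq$times_s, mean = means)
  if (!is.null(seq$concentration)) out$concentration_true <- seq$concentration
  structure(out, class = c("intensity_series", "data.frame"),
            roi = roi, background = NA_real_)
}

#' Subtract the zero-concentration background intensity
#'
#' An image of the tube with zero microbubble concentration retains a
#' residual (absorption) signal; subtracting its ROI mean makes zero
#' intensity correspond to zero microbubble concentration.
#'
#' @param series an \code{intensity_series}.
#' @param background scalar background ROI mean from the same acquisition
#'   settings.
#' @return the series with \code{mean} shifted by \code{-background}.
#' @export
subtract_background <- function(series, background) {
  stopifnot(inherits(series, "intensity_series"), is.numeric(background),
            length(background) == 1L)
  series$mean <- series$mean - background
  attr(series, "background") <- background
  series
}

#' Background ROI statistics from replicate bubble-free renders
#'
#' Renders \code{n_reps} frames of the bubble-free, water-filled tube with
#' photon noise and returns the mean and standard deviation of their ROI
#' means. The standard deviation is the noise level \eqn{\sigma} used for
#' the detection limit and the decay-fit noise floor.
#'
#' @param geometry,grid,curve,wp,materials,noise as in [render_frame()].
#' @param roi a [roi_rect()] result.
#' @param n_reps number of replicate frames.
#' @param seed integer seed.
#' @return list with \code{mean}, \code{sd} and the replicate \code{means}.
#' @export
background_roi_stats <- function(geometry, grid, curve, wp, roi,
                                 materials = phantom_materials(),
                                 noise = TRUE, n_reps = 8, seed = 1L) {
  dist0 <- size_distribution()
  means <- vapply(seq_len(n_reps), function(k) {
    ph <- generate_phantom(geometry, dist0, 0, seed = child_seed(seed, k))
    frame_roi_mean(render_frame(ph, grid, curve, wp, materials, noise,
                                seed = child_seed(seed, 1000L + k)), roi)
  }, numeric(1))
  list(mean = mean(means), sd = stats::sd(means), means = means)
}

#' Simulation-benchmarked intensity-concentration calibration
#'
#' Renders replicate dark-field frames at each requested concentration
#' (fresh phantom per replicate), extracts ROI means, and assembles the raw
#' and background-subtracted calibration curves. The zero-concentration
#' level is required: its replicates provide the background intensity and
#' the noise level \eqn{\sigma}.
#'
#' @param concentrations gas volume fractions; at least 3 distinct levels
#'   including 0.
#' @param geometry,dist,grid,curve,wp,materials,noise as elsewhere.
#' @param n_reps replicate frames per concentration level.
#' @param seed integer seed.
#' @return object of class \code{calibration_curve}: list with
#'   \code{data} (data.frame: concentration, mean_raw, mean_sub, se),
#'   \code{background}, \code{sigma}, \code{n_reps}, and (after
#'   [fit_linear()]) \code{fit}.
#' @export
build_calibration <- function(concentrations, geometry, dist, grid, curve,
                              wp, materials = phantom_materials(),
                              noise = TRUE, n_reps = 3, seed = 1L) {
  conc <- sort(unique(concentrations))
  if (length(conc) < 3) stop("need at least 3 distinct concentration levels")
  if (any(conc < 0)) stop("concentrations must be nonnegative")
  if (!any(conc == 0)) {
    stop("the zero-concentration level is required (background)")
  }
  roi <- roi_rect(grid, geometry)
  n0 <- max(n_reps, 8L)  # extra zero-level replicates stabilize sigma
  rep_means <- lapply(seq_along(conc), function(i) {
    nr <- if (conc[i] == 0) n0 else n_reps
    vapply(seq_len(nr), function(k) {
      ph <- generate_phantom(geometry, dist, conc[i],
                             seed = child_seed(seed, i * 1000L + 2L * k))
      frame_roi_mean(
        render_frame(ph, grid, curve, wp, materials, noise,
                     seed = child_seed(seed, i * 1000L + 2L * k + 1L)),
        roi)
    }, numeric(1))
  })
  background <- mean(rep_means[[which(conc == 0)]])
  sigma <- stats::sd(rep_means[[which(conc == 0)]])
  mean_raw <- vapply(rep_means, mean, numeric(1))
  se <- vapply(rep_means, function(v) stats::sd(v) / sqrt(length(v)),
               numeric(1))
  structure(
    list(data = data.frame(concentration = conc, mean_raw = mean_raw,
                           mean_sub = mean_raw - background, se = se),
         background = background, sigma = sigma, n_reps = n_reps,
         roi = roi, fit = NULL),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration: %d levels in [%.3g, %.3g], background %.4g, sigma %.3g>\n",
              nrow(x$data), min(x$data$concentration),
              max(x$data$concentration), x$background, x$sigma))
  if (!is.null(x$fit)) {
    cat(sprintf("  linear fit: slope %.4g, intercept %.3g, R^2 %.4f\n",
                x$fit$slope, x$fit$intercept, x$fit$r_squared))
  }
  invisible(x)
}

#' Ordinary least-squares line through the subtracted calibration
#'
#' Fits \code{mean_sub ~ concentration} by OLS and attaches slope,
#' intercept, residuals and \eqn{R^2} to the curve. The relation is only
#' approximately linear (multiple scattering saturates the dark-field
#' signal), so residuals are returned for diagnostics and are expected to
#' be structured rather than random-sign.
#'
#' @param curve a [build_calibration()] result.
#' @return the curve with a \code{fit} element
#'   (\code{slope}, \code{intercept}, \code{residuals}, \code{r_squared},
#'   \code{model}).
#' @export
fit_linear <- function(curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  d <- curve$data
  if (nrow(d) < 3) stop("need at least 3 calibration points")
  if (length(unique(d$concentration)) < 2) {
    stop("degenerate calibration: a single distinct concentration")
  }
  m <- stats::lm(mean_sub ~ concentration, data = d)
  curve$fit <- list(
    slope = unname(stats::coef(m)[2]),
    intercept = unname(stats::coef(m)[1]),
    residuals = unname(stats::residuals(m)),
    r_squared = summary(m)$r.squared,
    model = m
  )
  curve
}

#' Estimate concentration from a subtracted intensity
#'
#' Inverts the fitted calibration line, clipping below at zero. Values
#' beyond the calibrated intensity range trigger a warning (extrapolation).
#'
#' @param intensity background-subtracted ROI intensity (vectorized).
#' @param curve a fitted [fit_linear()] calibration curve.
#' @return estimated volume concentration(s), >= 0.
#' @export
estimate_concentration <- function(intensity, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (is.null(curve$fit)) {
    stop("calibration curve has not been fitted; call fit_linear() first")
  }
  rng <- range(curve$data$mean_sub)
  tol <- 0.05 * diff(rng)
  if (any(intensity < rng[1] - tol | intensity > rng[2] + tol)) {
    warning("intensity outside the calibrated range; extrapolating")
  }
  pmax(0, (intensity - curve$fit$intercept) / curve$fit$slope)
}

#' Recover the concentration decay constant from an intensity series
#'
#' Background-subtracts the ROI series, drops frames below the noise floor
#' (\code{noise_floor_mult} times the background \eqn{\sigma}, where the
#' log-transform becomes unstable), and fits
#' \eqn{\log(I - I_{bg}) = a - D t} by OLS. The returned confidence
#' interval is a seeded nonparametric bootstrap over frames.
#'
#' @param series an \code{intensity_series} of raw ROI means.
#' @param background scalar background ROI mean.
#' @param sigma_bg background noise level (sd of replicate background ROI
#'   means); 0 disables the noise floor.
#' @param noise_floor_mult noise-floor multiplier (default 3).
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level.
#' @param seed integer seed for the bootstrap.
#' @return list with \code{D_hat} (1/s), \code{ci} (two-sided), \code{n_used},
#'   \code{used} (logical per frame), \code{fit} (the lm object).
#' @export
estimate_decay_constant <- function(series, background, sigma_bg = 0,
                                    noise_floor_mult = 3, n_boot = 1000,
                                    conf = 0.95, seed = 1L) {
  stopifnot(inherits(series, "intensity_series"))
  if (nrow(series) < 8) stop("need at least 8 frames to estimate D")
  sub <- series$mean - background
  floor_ <- noise_floor_mult * sigma_bg
  used <- sub > floor_
  if (!any(used)) stop("no signal above background")
  if (sum(used) < 3) stop("fewer than 3 frames above the noise floor")
  s <- sub[used]
  t <- series$time_s[used]
  if (max(s) / min(s) < exp(1)) {
    stop("series spans less than one e-folding above background; ",
         "decay constant poorly identified")
  }
  fit <- stats::lm(log(s) ~ t)
  d_hat <- -unname(stats::coef(fit)[2])
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(length(s), replace = TRUE)
      if (length(unique(t[idx])) < 2) return(NA_real_)
      -unname(stats::coef(stats::lm(log(s[idx]) ~ t[idx]))[2])
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE,
                        names = FALSE)
  list(D_hat = d_hat, ci = ci, n_used = sum(used), used = used, fit = fit)
}

#' Rose-criterion detection limit
#'
#' The smallest concentration whose background-subtracted signal reaches
#' \code{snr_threshold} times the noise level, obtained by inverting the
#' calibration line: \eqn{c_{min} = k\,\sigma/\mathrm{slope}}. The Rose
#' criterion takes \eqn{k = 5} as the threshold at which a detail is
#' reliably distinguished. \eqn{\sigma} is the standard deviation of
#' replicate zero-concentration ROI means (stated in the curve metadata).
#'
#' @param curve a fitted [fit_linear()] calibration curve.
#' @param snr_threshold signal-to-noise threshold (default 5).
#' @return detection-limit volume concentration.
#' @export
detection_limit <- function(curve, snr_threshold = 5) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (is.null(curve$fit)) {
    stop("calibration curve has not been fitted; call fit_linear() first")
  }
  if (curve$fit$slope <= 0) {
    stop("non-positive calibration slope; detection limit undefined")
  }
  snr_threshold * curve$sigma / curve$fit$slope
}

#' Align intensity series at a common intensity level
#'
#' Experimental runs that cannot start at identical concentrations are
#' displayed with t = 0 set where their intensities overlap; this utility
#' reproduces that convention by shifting each series' time axis so that
#' its (linearly interpolated) crossing of \code{level} sits at zero.
#'
#' @param series_list list of \code{intensity_series}.
#' @param level intensity level defining t = 0; defaults to the highest
#'   intensity reached by every series.
#' @return the list with shifted \code{time_s} columns.
#' @export
align_at_intensity <- function(series_list, level = NULL) {
  stopifnot(length(series_list) >= 1)
  if (is.null(level)) {
    level <- min(vapply(series_list, function(s) max(s$mean), numeric(1)))
  }
  lapply(series_list, function(s) {
    below <- which(s$mean <= level)
    if (!length(below) || below[1] == 1L) {
      t0 <- s$time_s[1]
    } else {
      i <- below[1]
      # linear interpolation between the bracketing frames
      t0 <- s$time_s[i - 1] + (s$mean[i - 1] - level) /
        (s$mean[i - 1] - s$mean[i]) * (s$time_s[i] - s$time_s[i - 1])
    }
    s$time_s <- s$time_s - t0
    s
  })
}
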