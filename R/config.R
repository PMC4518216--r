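#' Default run configuration
#'
#' All defaults reproduce the reference acquisition: 17 keV beam, 4 mm ID
#' nylon tube, 9 um pixels with 4x4 binning, 0.5 s exposure + 0.27 s
#' readout (0.77 s frame period), analyser parked at 5\% reflectivity on
#' the positive rocking-curve tail, microbubbles of 4 um median radius.
#'
#' @return nested named list (see sections: \code{beam},
#'   \code{rocking_curve}, \code{geometry}, \code{bubbles},
#'   \code{detector}, \code{timing}, \code{dilution}, \code{sequence},
#'   \code{quantify}, \code{seed}).
#' @export
default_config <- function() {
  list(
    beam = list(energy_kev = 17),
    rocking_curve = list(shape = "gaussian", fwhm_urad = 20,
                         peak_reflectivity = 1.0, eta = 0.3,
                         working_level = 0.05, side = "positive"),
    geometry = list(inner_diameter_mm = 4, wall_thickness_mm = 1),
    bubbles = list(median_radius_um = 4, geometric_sd = 1.7,
                   min_radius_um = 1, max_radius_um = 16),
    detector = list(pixel_um = 9, binning = 4L, n_rows = 128L, n_cols = 64L,
                    rays_per_pixel = 64L, photons_per_pixel = 1e4,
                    noise = TRUE),
    timing = list(exposure_s = 0.5, readout_s = 0.27),
    dilution = list(C1 = 0.01, D = 0.056, Q = NULL, V_p = 2.3, V_l = 2.8,
                    R = NULL),
    sequence = list(n_frames = 40L),
    quantify = list(roi_lumen_fraction = 0.5, snr_threshold = 5,
                    noise_floor_mult = 3, n_boot = 1000L,
                    calibration_levels = c(0, 0.00125, 0.0025, 0.005,
                                           0.0075, 0.01),
                    n_reps = 3L),
    seed = 1L
  )
}

#' Load (and validate) a run configuration
#'
#' Reads a YAML configuration file, fills unspecified values from
#' [default_config()], and rejects unknown keys with their full path. An
#' empty file yields the all-defaults configuration.
#'
#' @param path YAML file path.
#' @return validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(default_config(), user, path = character(0))
  validate_config(cfg)
  cfg
}

#' Save a configuration as YAML
#'
#' @param config configuration list.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# recursive merge with unknown-key rejection; NULL defaults (optional keys)
# accept any scalar
merge_config <- function(def, user, path) {
  if (!is.list(user)) {
    stop("config section '", paste(path, collapse = "."),
         "' must be a mapping")
  }
  unknown <- setdiff(names(user), names(def))
  if (length(unknown)) {
    stop("unknown config key: ",
         paste(paste(c(path, unknown[1]), collapse = "."), collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      def[[k]] <- merge_config(def[[k]], user[[k]], c(path, k))
    } else {
      def[k] <- list(user[[k]])  # preserves explicit NULLs (optional keys)
    }
  }
  def
}

validate_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid config field '", field, "': ", msg)
  }
  chk(cfg$beam$energy_kev > 0, "beam.energy_kev", "must be positive")
  chk(cfg$rocking_curve$fwhm_urad > 0, "rocking_curve.fwhm_urad",
      "must be positive")
  lvl <- cfg$rocking_curve$working_level
  chk(lvl > 0 && lvl < 1, "rocking_curve.working_level",
      "must be strictly between 0 and 1")
  chk(cfg$geometry$inner_diameter_mm > 0, "geometry.inner_diameter_mm",
      "must be positive")
  chk(cfg$geometry$wall_thickness_mm > 0, "geometry.wall_thickness_mm",
      "must be positive")
  chk(cfg$bubbles$median_radius_um > 0, "bubbles.median_radius_um",
      "must be positive")
  chk(cfg$bubbles$min_radius_um < cfg$bubbles$max_radius_um,
      "bubbles.min_radius_um", "truncation bounds out of order")
  chk(cfg$timing$exposure_s >= 0, "timing.exposure_s",
      "must be nonnegative")
  chk(cfg$timing$readout_s >= 0, "timing.readout_s", "must be nonnegative")
  chk(cfg$detector$rays_per_pixel >= 1, "detector.rays_per_pixel",
      "must be >= 1")
  chk(cfg$dilution$C1 >= 0, "dilution.C1", "must be nonnegative")
  if (!is.null(cfg$dilution$D)) {
    chk(cfg$dilution$D >= 0, "dilution.D", "must be nonnegative")
  }
  chk(cfg$sequence$n_frames >= 1, "sequence.n_frames", "must be >= 1")
  fr <- cfg$quantify$roi_lumen_fraction
  chk(fr > 0 && fr < 1, "quantify.roi_lumen_fraction",
      "must be strictly between 0 and 1")
  invisible(cfg)
}
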