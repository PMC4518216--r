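#' Detector grid
#'
#' Binned CCD geometry: 9 um raw pixels with 4x4 binning give 36 um
#' effective pixels. Image rows run across the tube (y, the diffraction
#' plane direction, centred on the vessel axis); columns run along the
#' vessel axis (x, starting at x = 0).
#'
#' @param pixel_um raw pixel size, micrometre.
#' @param binning integer binning factor; effective pixel =
#'   \code{pixel_um * binning}.
#' @param n_rows,n_cols image size in effective pixels.
#' @param rays_per_pixel rays launched per effective pixel on a jittered
#'   subgrid; controls refraction sampling noise only (attenuation is
#'   deterministic per ray).
#' @param photons_per_pixel incident photon budget per effective pixel used
#'   when Poisson noise is enabled.
#' @return object of class \code{detector_grid}.
#' @export
detector_grid <- function(pixel_um = 9, binning = 4L, n_rows = 128L,
                          n_cols = 64L, rays_per_pixel = 64L,
                          photons_per_pixel = 1e4) {
  stopifnot(pixel_um > 0, binning >= 1, n_rows >= 1, n_cols >= 1,
            rays_per_pixel >= 1, photons_per_pixel > 0)
  structure(
    list(pixel_um = pixel_um, binning = as.integer(binning),
         pixel_eff_um = pixel_um * binning,
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         rays_per_pixel = as.integer(rays_per_pixel),
         photons_per_pixel = photons_per_pixel),
    class = "detector_grid"
  )
}

#' @export
print.detector_grid <- function(x, ...) {
  cat(sprintf(
    "<detector: %d x %d px of %g um (%g um raw, %dx binning), %d rays/px>\n",
    x$n_rows, x$n_cols, x$pixel_eff_um, x$pixel_um, x$binning,
    x$rays_per_pixel))
  invisible(x)
}

#' Field of view of a detector grid, mm
#'
#' @param grid a [detector_grid()].
#' @return named vector \code{c(width_mm, height_mm)} (width along the
#'   vessel axis, height across it).
#' @export
field_of_view <- function(grid) {
  stopifnot(inherits(grid, "detector_grid"))
  c(width_mm = grid$n_cols * grid$pixel_eff_um * 1e-3,
    height_mm = grid$n_rows * grid$pixel_eff_um * 1e-3)
}

#' Closed-form refractive deflection of a ray crossing a sphere
#'
#' A ray traversing a sphere of refractive-index contrast
#' \eqn{\Delta\delta} at impact parameter \eqn{b} is deviated by
#' \eqn{2\,\Delta\delta\, b/\sqrt{r^2-b^2}} (entry plus exit refraction).
#' This is the independent analytic oracle for the numerical tracer.
#'
#' @param delta_contrast refractive-index decrement difference across the
#'   sphere surface (dimensionless, e.g. \code{8e-7} for gas in water at
#'   17 keV).
#' @param radius_um sphere radius, micrometre.
#' @param impact_um impact parameter, micrometre; must satisfy
#'   \code{0 <= impact_um < radius_um}.
#' @return deflection magnitude in microradian.
#' @examples
#' sphere_deflection_closed_form(8e-7, 4, 4 / sqrt(2))  # ~1.6 urad
#' @export
sphere_deflection_closed_form <- function(delta_contrast, radius_um,
                                          impact_um) {
  stopifnot(radius_um > 0)
  if (any(impact_um < 0) || any(impact_um >= radius_um)) {
    stop("impact parameter must satisfy 0 <= b < radius")
  }
  2 * abs(delta_contrast) * impact_um /
    sqrt(radius_um^2 - impact_um^2) * 1e6
}

#' Material set for the standard phantom
#'
#' Convenience lookup of all materials the tracer needs at one energy.
#'
#' @param energy_kev photon energy, keV.
#' @return named list of [optical_constants()] results: \code{lumen} (water),
#'   \code{wall} (nylon-12), \code{gas} (gas core, vacuum convention),
#'   \code{ambient} (air).
#' @export
phantom_materials <- function(energy_kev = 17) {
  list(lumen = optical_constants("water", energy_kev),
       wall = optical_constants("nylon12", energy_kev),
       gas = optical_constants("gas_core", energy_kev),
       ambient = optical_constants("air", energy_kev))
}

#' Trace a single ray through a phantom
#'
#' Thin wrapper over the vectorized tracer, useful for inspecting the
#' physics of individual rays (see [sphere_deflection_closed_form()] for the
#' analytic single-sphere oracle).
#'
#' @param ray list with \code{x_mm}, \code{y_mm} (entrance position;
#'   propagation is along +z).
#' @param phantom a [generate_phantom()] result (or \code{NULL} for no
#'   sample).
#' @param materials a [phantom_materials()] list.
#' @return the ray augmented with \code{weight} (transmission in [0, 1]) and
#'   \code{deflection_urad} (diffraction-plane angular deviation).
#' @export
trace_ray <- function(ray, phantom, materials = phantom_materials()) {
  res <- trace_batch(ray$x_mm, ray$y_mm, phantom, materials)
  ray$weight <- res$weight
  ray$deflection_urad <- res$defl_urad
  ray
}

# vectorized trace used by both trace_ray and render_frame
trace_batch <- function(x_mm, y_mm, phantom, materials) {
  if (is.null(phantom)) {
    return(list(weight = rep(1, length(x_mm)),
                defl_urad = rep(0, length(x_mm))))
  }
  stopifnot(inherits(phantom, "phantom"))
  g <- phantom$geometry
  sp <- phantom$spheres
  trace_rays_cpp(x_mm, y_mm, sp$x, sp$y, sp$r,
                 Ri = g$inner_diameter_mm / 2,
                 Ro = g$inner_diameter_mm / 2 + g$wall_thickness_mm,
                 L = g$length_mm,
                 mu_wall = materials$wall$mu, mu_lumen = materials$lumen$mu,
                 mu_gas = materials$gas$mu,
                 delta_wall = materials$wall$delta,
                 delta_lumen = materials$lumen$delta,
                 delta_gas = materials$gas$delta,
                 delta_ambient = materials$ambient$delta)
}

#' Render one dark-field frame
#'
#' Launches \code{rays_per_pixel} rays per effective pixel on a jittered
#' subgrid, traces each through the phantom, and records the mean over rays
#' of \code{weight * reflectivity(curve, offset - deflection)} -- the
#' analyser acting as an angular filter at the tail working point. Optional
#' per-pixel Poisson noise uses the grid's photon budget.
#'
#' Intensities are normalized to unit incident flux: with no sample and no
#' noise every pixel equals the working-point reflectivity.
#'
#' @param phantom a [generate_phantom()] result, or \code{NULL} for a
#'   sample-free flat field.
#' @param grid a [detector_grid()].
#' @param curve a [rocking_curve()].
#' @param wp a [find_working_point()] result.
#' @param materials a [phantom_materials()] list.
#' @param noise logical; apply Poisson photon noise.
#' @param seed integer seed (jitter pattern and noise).
#' @param timestamp_s optional acquisition time recorded on the frame.
#' @return an \code{image_frame}: numeric matrix (rows = across tube) with
#'   attributes \code{timestamp_s}, \code{concentration}, \code{noise},
#'   \code{photons_per_pixel}.
#' @export
render_frame <- function(phantom, grid, curve, wp,
                         materials = phantom_materials(), noise = FALSE,
                         seed = NULL, timestamp_s = NA_real_) {
  stopifnot(inherits(grid, "detector_grid"), inherits(curve, "rocking_curve"),
            inherits(wp, "working_point"))
  if (!is.null(phantom)) {
    fov <- field_of_view(grid)
    if (phantom$geometry$length_mm < fov[["width_mm"]] - 1e-9) {
      stop("phantom segment (", phantom$geometry$length_mm,
           " mm) shorter than the detector field of view (",
           fov[["width_mm"]], " mm)")
    }
  }
  p_mm <- grid$pixel_eff_um * 1e-3
  rpp <- grid$rays_per_pixel
  npix <- grid$n_rows * grid$n_cols
  with_seed(seed, {
    # jittered subgrid: factor rpp into near-square gy x gx
    gy <- max(1L, as.integer(floor(sqrt(rpp))))
    while (rpp %% gy != 0L) gy <- gy - 1L
    gx <- rpp %/% gy
    # pixel centres
    col_x <- (seq_len(grid$n_cols) - 0.5) * p_mm          # along axis
    row_y <- (grid$n_rows / 2 - seq_len(grid$n_rows) + 0.5) * p_mm
    # subray offsets within a pixel, stratified + jittered
    ox <- (rep(seq_len(gx), times = gy) - 1) / gx
    oy <- (rep(seq_len(gy), each = gx) - 1) / gy
    # layout: rays vary fastest, then rows, then cols
    x0 <- rep(col_x, each = grid$n_rows * rpp)
    y0 <- rep(rep(row_y, each = rpp), times = grid$n_cols)
    jx <- (rep_len(ox, npix * rpp) + stats::runif(npix * rpp) / gx - 0.5) * p_mm
    jy <- (rep_len(oy, npix * rpp) + stats::runif(npix * rpp) / gy - 0.5) * p_mm
    tr <- trace_batch(x0 + jx, y0 + jy, phantom, materials)
    refl <- reflectivity(curve, wp$offset_urad - tr$defl_urad)
    sig <- tr$weight * refl
    img <- matrix(colMeans(matrix(sig, nrow = rpp)),
                  nrow = grid$n_rows, ncol = grid$n_cols)
    if (isTRUE(noise)) {
      nph <- grid$photons_per_pixel
      img <- matrix(stats::rpois(npix, img * nph) / nph,
                    nrow = grid$n_rows, ncol = grid$n_cols)
    }
    structure(img, class = c("image_frame", "matrix", "array"),
              timestamp_s = timestamp_s,
              concentration = if (is.null(phantom)) 0 else
                phantom$realized_concentration,
              noise = isTRUE(noise),
              photons_per_pixel = if (isTRUE(noise))
                grid$photons_per_pixel else NA_real_)
  })
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf(
    "<image frame %d x %d, t = %s s, concentration %s, noise %s>\n",
    nrow(x), ncol(x), format(attr(x, "timestamp_s")),
    format(attr(x, "concentration")), attr(x, "noise")))
  invisible(x)
}

#' Render a dark-field image sequence of a decaying suspension
#'
#' Frame k is rendered from a fresh phantom realization at concentration
#' \eqn{C(t_k)}, with \eqn{t_k} the mid-exposure time of frame k: the flow
#' replaces the bubble population between frames, so successive frames are
#' independent draws of the sphere pack at a decaying concentration.
#'
#' @param geometry a [vessel_geometry()].
#' @param dist a [size_distribution()].
#' @param dilution a [dilution_model()].
#' @param timing an [acquisition_timing()].
#' @param n_frames number of frames (>= 1).
#' @param grid,curve,wp,materials,noise as in [render_frame()].
#' @param seed integer master seed; per-frame phantom/noise seeds are
#'   derived from it.
#' @return an \code{image_sequence}: list with \code{frames} (list of
#'   \code{image_frame}), \code{times_s}, \code{concentration} (ground
#'   truth per frame), \code{dilution}, \code{timing}, \code{grid}.
#' @export
render_sequence <- function(geometry, dist, dilution, timing, n_frames,
                            grid, curve, wp,
                            materials = phantom_materials(), noise = TRUE,
                            seed = 1L) {
  stopifnot(n_frames >= 1)
  times <- frame_times(timing, n_frames)
  conc <- concentration_at(dilution, times)
  frames <- vector("list", n_frames)
  for (k in seq_len(n_frames)) {
    ph <- generate_phantom(geometry, dist, conc[k],
                           seed = child_seed(seed, 2L * k))
    frames[[k]] <- render_frame(ph, grid, curve, wp, materials, noise,
                                seed = child_seed(seed, 2L * k + 1L),
                                timestamp_s = times[k])
  }
  structure(
    list(frames = frames, times_s = times, concentration = conc,
         dilution = dilution, timing = timing, grid = grid, seed = seed),
    class = "image_sequence"
  )
}

#' @export
print.image_sequence <- function(x, ...) {
  cat(sprintf(
    "<image sequence: %d frames of %d x %d, t = %.3g..%.3g s, C = %.3g..%.3g>\n",
    length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
    min(x$times_s), max(x$times_s),
    max(x$concentration), min(x$concentration)))
  invisible(x)
}

#' Write / read an image sequence as multi-page TIFF plus sidecar CSV
#'
#' Frames go to a 32-bit float multi-page TIFF; timestamps and ground-truth
#' concentrations go to a plain-text sidecar CSV (columns \code{frame},
#' \code{time_s}, \code{concentration}).
#'
#' @param seq an \code{image_sequence}.
#' @param tiff_path,csv_path output paths.
#' @return list of the two paths, invisibly.
#' @export
write_sequence <- function(seq, tiff_path, csv_path) {
  stopifnot(inherits(seq, "image_sequence"))
  pages <- lapply(seq$frames, function(f) {
    m <- unclass(f)
    attributes(m) <- list(dim = dim(m))
    m
  })
  tiff::writeTIFF(pages, tiff_path, bits.per.sample = 32L, reduce = FALSE)
  utils::write.csv(
    data.frame(frame = seq_along(seq$frames), time_s = seq$times_s,
               concentration = seq$concentration),
    csv_path, row.names = FALSE)
  invisible(list(tiff = tiff_path, csv = csv_path))
}

#' @rdname write_sequence
#' @export
read_sequence <- function(tiff_path, csv_path) {
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  meta <- utils::read.csv(csv_path)
  stopifnot(length(pages) == nrow(meta))
  frames <- lapply(seq_along(pages), function(k) {
    structure(pages[[k]], class = c("image_frame", "matrix", "array"),
              timestamp_s = meta$time_s[k],
              concentration = meta$concentration[k],
              noise = NA, photons_per_pixel = NA_real_)
  })
  structure(
    list(frames = frames, times_s = meta$time_s,
         concentration = meta$concentration,
         dilution = NULL, timing = NULL, grid = NULL, seed = NA_integer_),
    class = "image_sequence"
  )
}
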