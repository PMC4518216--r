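#' Microbubble size distribution
#'
#' Polymer-shell microbubbles of the Expancel type have a median radius of
#' 4 um; the full measured distribution is not published, so a truncated
#' lognormal stands in, with the geometric standard deviation as a declared
#' assumption (default 1.7, typical of this class of agent). The default
#' truncation bounds (1, 16) um are symmetric about the median on the log
#' scale, so truncation leaves the median unchanged.
#'
#' @param family only \code{"lognormal"} is implemented.
#' @param median_radius_um median bubble radius, micrometre.
#' @param geometric_sd geometric standard deviation (> 1 for spread; values
#'   approaching 1 give a near-monodisperse population).
#' @param min_radius_um,max_radius_um truncation bounds, micrometre.
#' @return object of class \code{size_distribution}.
#' @export
size_distribution <- function(family = "lognormal", median_radius_um = 4,
                              geometric_sd = 1.7, min_radius_um = 1,
                              max_radius_um = 16) {
  family <- match.arg(family)
  stopifnot(median_radius_um > 0, geometric_sd >= 1)
  if (min_radius_um >= max_radius_um) {
    stop("invalid truncation: min_radius_um (", min_radius_um,
         ") must be < max_radius_um (", max_radius_um, ")")
  }
  stopifnot(min_radius_um > 0)
  structure(
    list(family = family, median_radius_um = median_radius_um,
         geometric_sd = geometric_sd, min_radius_um = min_radius_um,
         max_radius_um = max_radius_um),
    class = "size_distribution"
  )
}

#' Sample bubble radii
#'
#' Draws radii from the truncated lognormal by inverse-CDF sampling, which
#' is exact and consumes one uniform deviate per radius.
#'
#' @param dist a [size_distribution()].
#' @param n number of radii.
#' @param seed optional integer; fixed seed gives identical draws.
#' @return numeric vector of radii in micrometre, within the truncation
#'   bounds.
#' @export
sample_radii <- function(dist, n, seed = NULL) {
  stopifnot(inherits(dist, "size_distribution"), n >= 0)
  if (n == 0) return(numeric(0))
  mulog <- log(dist$median_radius_um)
  sdlog <- log(dist$geometric_sd)
  if (sdlog < 1e-12) return(rep(dist$median_radius_um, n))
  plo <- stats::plnorm(dist$min_radius_um, mulog, sdlog)
  phi <- stats::plnorm(dist$max_radius_um, mulog, sdlog)
  with_seed(seed, {
    u <- stats::runif(n, plo, phi)
    stats::qlnorm(u, mulog, sdlog)
  })
}

#' Vessel geometry
#'
#' A straight cylindrical tube modelling a blood vessel: Nylon-12 wall,
#' water-filled lumen. Axis conventions: the beam propagates along +z, the
#' vessel axis lies along x (perpendicular to the beam), and the analyser
#' diffraction plane is y--z, so the crystal senses angular deviations in y.
#'
#' @param inner_diameter_mm lumen diameter (default 4, an adult coronary
#'   artery scale).
#' @param wall_thickness_mm tube wall (default 1, typical of 4 mm ID
#'   nylon tubing).
#' @param length_mm imaged segment length along the vessel axis.
#' @return object of class \code{vessel_geometry}.
#' @export
vessel_geometry <- function(inner_diameter_mm = 4, wall_thickness_mm = 1,
                            length_mm = 2.304) {
  stopifnot(inner_diameter_mm > 0, wall_thickness_mm > 0, length_mm > 0)
  structure(
    list(inner_diameter_mm = inner_diameter_mm,
         wall_thickness_mm = wall_thickness_mm,
         length_mm = length_mm),
    class = "vessel_geometry"
  )
}

#' Lumen volume of a vessel segment
#'
#' @param geometry a [vessel_geometry()].
#' @return volume in mm^3: \eqn{\pi (d/2)^2 L}.
#' @export
lumen_volume <- function(geometry) {
  stopifnot(inherits(geometry, "vessel_geometry"))
  pi * (geometry$inner_diameter_mm / 2)^2 * geometry$length_mm
}

#' Generate a random microbubble phantom
#'
#' Places a random, non-overlapping pack of polydisperse gas spheres
#' uniformly in the vessel lumen at a target gas volume fraction. Radii are
#' drawn first until their summed volume reaches the target, fixing the
#' realized concentration; centres are then placed by sequential rejection
#' sampling (uniform in the lumen, rejecting wall protrusion and overlap),
#' which terminates comfortably at the dilute concentrations of interest
#' (<= a few percent by volume).
#'
#' @param geometry a [vessel_geometry()].
#' @param dist a [size_distribution()].
#' @param concentration target gas volume fraction of the lumen, in
#'   \code{[0, 0.05]}.
#' @param seed integer seed; identical seed and parameters give an
#'   identical sphere list.
#' @return object of class \code{phantom}: list with \code{geometry},
#'   \code{spheres} (data.frame \code{x,y,z} mm, \code{r} mm),
#'   \code{target_concentration}, \code{realized_concentration}, \code{seed}.
#' @export
generate_phantom <- function(geometry, dist, concentration, seed = 1L) {
  stopifnot(inherits(geometry, "vessel_geometry"),
            inherits(dist, "size_distribution"))
  if (!is.numeric(concentration) || concentration < 0) {
    stop("concentration must be nonnegative")
  }
  if (concentration > 0.05) {
    stop("concentration ", concentration, " above the supported dilute",
         " packing limit (0.05); rejection packing is not guaranteed there")
  }
  vol <- lumen_volume(geometry)
  target_vol <- concentration * vol
  res <- with_seed(seed, {
    if (target_vol == 0) {
      list(spheres = empty_spheres(), realized = 0)
    } else {
      # draw radii in chunks until the cumulative volume reaches target
      r_um <- numeric(0)
      mean_vol <- (4 / 3) * pi * (dist$median_radius_um * 1e-3)^3 *
        exp(4.5 * log(dist$geometric_sd)^2)  # lognormal E[r^3] factor
      repeat {
        need <- target_vol - sum((4 / 3) * pi * (r_um * 1e-3)^3)
        if (need <= 0) break
        chunk <- max(1000L, ceiling(1.1 * need / mean_vol))
        r_um <- c(r_um, sample_radii(dist, chunk))
      }
      v <- (4 / 3) * pi * (r_um * 1e-3)^3
      n <- which(cumsum(v) >= target_vol)[1]
      r_mm <- r_um[seq_len(n)] * 1e-3
      pos <- pack_spheres_cpp(r_mm, geometry$inner_diameter_mm / 2,
                              geometry$length_mm, 5000L)
      list(spheres = data.frame(x = pos$x, y = pos$y, z = pos$z, r = r_mm),
           realized = sum((4 / 3) * pi * r_mm^3) / vol)
    }
  })
  structure(
    list(geometry = geometry, dist = dist, spheres = res$spheres,
         target_concentration = concentration,
         realized_concentration = res$realized, seed = seed),
    class = "phantom"
  )
}

empty_spheres <- function() {
  data.frame(x = numeric(0), y = numeric(0), z = numeric(0), r = numeric(0))
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(paste0(
    "<phantom: %d spheres in %.3g mm ID x %.3g mm tube segment,\n",
    "  gas volume fraction %.4g (target %.4g), seed %s>\n"),
    nrow(x$spheres), x$geometry$inner_diameter_mm, x$geometry$length_mm,
    x$realized_concentration, x$target_concentration, format(x$seed)))
  invisible(x)
}

#' Serialize / read a phantom as plain-text CSV
#'
#' A commented header block carries the geometry, seed and concentrations;
#' the body holds sphere centres (mm) and radii (um). Round-trips through
#' [read_phantom_csv()].
#'
#' @param phantom a [generate_phantom()] result.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_phantom_csv <- function(phantom, path) {
  stopifnot(inherits(phantom, "phantom"))
  g <- phantom$geometry
  hdr <- c(
    sprintf("# inner_diameter_mm: %.17g", g$inner_diameter_mm),
    sprintf("# wall_thickness_mm: %.17g", g$wall_thickness_mm),
    sprintf("# length_mm: %.17g", g$length_mm),
    sprintf("# target_concentration: %.17g", phantom$target_concentration),
    sprintf("# realized_concentration: %.17g", phantom$realized_concentration),
    sprintf("# seed: %d", as.integer(phantom$seed))
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- phantom$spheres
  out <- data.frame(x_mm = df$x, y_mm = df$y, z_mm = df$z,
                    radius_um = df$r * 1e3)
  utils::write.csv(format(out, digits = 17, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_phantom_csv
#' @param dist size distribution to attach to the restored phantom (the
#'   distribution itself is not serialized).
#' @export
read_phantom_csv <- function(path, dist = size_distribution()) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    as.numeric(sub(paste0("^# ", key, ": *"), "", ln))
  }
  geometry <- vessel_geometry(getv("inner_diameter_mm"),
                              getv("wall_thickness_mm"), getv("length_mm"))
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  spheres <- if (nrow(body)) {
    data.frame(x = body$x_mm, y = body$y_mm, z = body$z_mm,
               r = body$radius_um * 1e-3)
  } else empty_spheres()
  structure(
    list(geometry = geometry, dist = dist, spheres = spheres,
         target_concentration = getv("target_concentration"),
         realized_concentration = getv("realized_concentration"),
         seed = as.integer(getv("seed"))),
    class = "phantom"
  )
}
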