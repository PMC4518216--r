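# shared fixtures: small, fast variants of the standard setup

std_materials <- phantom_materials(17)
std_curve <- rocking_curve(fwhm_urad = 20)
std_wp <- find_working_point(std_curve, 0.05)

# reduced-resolution detector used throughout the unit tests; the
# full-resolution study settings live in test-acceptance.R
small_grid <- function(rays_per_pixel = 16L, n_rows = 96L, n_cols = 32L) {
  detector_grid(pixel_um = 9, binning = 4L, n_rows = n_rows,
                n_cols = n_cols, rays_per_pixel = rays_per_pixel)
}

small_geometry <- function(grid = small_grid()) {
  vessel_geometry(inner_diameter_mm = 4, wall_thickness_mm = 1,
                  length_mm = field_of_view(grid)[["width_mm"]])
}

# a bare intensity_series for fits that do not need rendered images
make_series <- function(time_s, mean) {
  structure(data.frame(time_s = time_s, mean = mean),
            class = c("intensity_series", "data.frame"),
            roi = NULL, background = NA_real_)
}

# brute-force all-pairs overlap count (independent of the packing grid)
count_overlaps <- function(phantom) {
  sp <- phantom$spheres
  n <- nrow(sp)
  if (n < 2) return(0L)
  bad <- 0L
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    d2 <- (sp$x[j] - sp$x[i])^2 + (sp$y[j] - sp$y[i])^2 +
      (sp$z[j] - sp$z[i])^2
    bad <- bad + sum(d2 < (sp$r[j] + sp$r[i])^2 * (1 - 1e-12))
  }
  bad
}
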