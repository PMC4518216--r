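# mbxpci

Simulation and quantification of **microbubble contrast agents in
dark-field x-ray phase-contrast imaging (XPCi)**.

## The problem

Microbubbles — micron-scale gas cores in a polymer or surfactant shell —
are clinical ultrasound contrast agents that can be functionalised to
target specific biological processes. They also scatter x-rays: each
bubble refracts the beam by microradians, and a population of bubbles
produces ultra-small-angle scatter that an analyser-based imaging (ABI)
system converts into measurable contrast. With the analyser crystal parked
on the *tail* of its rocking curve (5 % reflectivity — the "single-shot
dark-field" configuration), the unscattered beam is largely rejected and
the bubble-laden lumen of a vessel appears *bright*. If the detected
intensity can be mapped back to bubble concentration, dark-field XPCi
becomes a quantitative, dynamic, functional imaging modality.

This package implements the full computational chain for that idea, for
researchers in phase-contrast imaging and contrast-agent development:

* **`optics`** — x-ray optical constants (δ, μ) of the phantom materials at
  15–20 keV (bundled plain-text table) and a parametric rocking-curve model
  with its tail working point;
* **`phantom`** — reproducible 3-D phantoms: a 4 mm ID Nylon-12 tube whose
  water lumen holds a random non-overlapping pack of polydisperse gas
  microspheres (truncated lognormal, median radius 4 μm) at a target volume
  fraction;
* **`darkfield`** — a ray-optics Monte Carlo forward model: parallel 17 keV
  rays are attenuated and refracted at every interface, the diffraction-plane
  deflection is pushed through the rocking curve at the working point, and
  the result is binned into 36 μm effective detector pixels (9 μm CCD,
  4×4 binning) with optional Poisson noise;
* **`flow_model`** — well-mixed loop dilution kinetics
  C(t) = C₁·exp(−D·t) and the 0.5 s exposure / 0.27 s readout frame timing;
* **`quantify`** — ROI intensity series, background subtraction,
  intensity–concentration calibration with linear fit and residual
  diagnostics, Rose-criterion (SNR = 5) detection limit
  c_min = 5·σ/slope, and log-linear recovery of D with a bootstrap
  confidence interval.

The key physics primitive is the refraction of a ray crossing a sphere of
refractive-index-decrement contrast Δδ at impact parameter *b*:

    Δθ = 2·Δδ·b / √(r² − b²)

(entry plus exit, directed toward the bubble axis — a gas bubble in water
is a weak converging x-ray lens). This closed form doubles as the
independent oracle for the numerical tracer in the test suite.

## Worked example

```r
library(mbxpci)

curve <- rocking_curve(fwhm_urad = 20)          # parametric analyser curve
wp <- find_working_point(curve, level = 0.05)   # dark-field working point
wp
#> <working point: 20.79 urad (positive tail, 0.05 x peak)>

grid <- detector_grid(n_rows = 128, n_cols = 64, rays_per_pixel = 32)
geom <- vessel_geometry(length_mm = field_of_view(grid)[["width_mm"]])
mat  <- phantom_materials(17)
dist <- size_distribution()
roi  <- roi_rect(grid, geom)

ph <- generate_phantom(geom, dist, concentration = 0.005, seed = 1)
ph
#> <phantom: 178693 spheres in 4 mm ID x 2.3 mm tube segment,
#>   gas volume fraction 0.005001 (target 0.005), seed 1>

bg <- render_frame(generate_phantom(geom, dist, 0, seed = 2),
                   grid, curve, wp, mat)
fr <- render_frame(ph, grid, curve, wp, mat)
round(frame_roi_mean(fr, roi) / frame_roi_mean(bg, roi), 3)
#> [1] 1.396
```

A gas volume fraction of 0.005 brightens the central-tube ROI by ~40 %
over the bubble-free background. Simulating a full dilution run and
recovering its decay constant:

```r
sq <- render_sequence(geom, dist, dilution_model(C1 = 0.01, D = 0.056),
                      acquisition_timing(), n_frames = 40, grid, curve, wp,
                      mat, noise = TRUE, seed = 11)
ser <- roi_mean_series(sq, roi)
est <- estimate_decay_constant(ser, background = frame_roi_mean(bg, roi),
                               sigma_bg = 2e-5, seed = 1)
round(c(D_hat = est$D_hat, est$ci), 4)
#>  D_hat
#> 0.0540 0.0534 0.0547
```

The true decay constant 0.056 s⁻¹ is recovered within a few percent; the
small negative bias reflects the mild saturation of the dark-field signal
at higher concentrations (visible as structured residuals in the
calibration fit).

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
study's result chain; each writes tables (and figures, when `ggplot2` is
available) under `results/`:

1. `01_simulate_sequence.R` — reference dynamic run (D = 0.056 s⁻¹),
   sequence TIFF + frame montage;
2. `02_decay_runs.R` — three runs with different valve-controlled D,
   aligned intensity–time series;
3. `03_calibration.R` — intensity–concentration calibration, linear fit,
   residuals, Rose detection limit;
4. `04_recover_decay.R` — reads the stored sequences back, converts
   intensity to concentration and recovers each run's D with its CI.

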