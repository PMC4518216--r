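---
title: "Dark-field XPCi of microbubbles: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dark-field XPCi of microbubbles: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbxpci)
```

## The imaging model

Analyser-based imaging (ABI) places a perfect crystal between sample and
detector. The crystal reflects only rays within a microradian-wide angular
window — its *rocking curve* — so angular deviations imprinted on the beam
by the sample become intensity modulations. In the single-shot *dark-field*
configuration the crystal is parked on the rocking-curve tail where
reflectivity is 5 % of peak: the nearly-undeviated primary beam is largely
rejected, and rays scattered through microradian angles toward the peak are
*amplified* relative to it.

A microbubble is a gas sphere in water. At 17 keV the refractive index is
$n = 1 - \delta$ with $\delta_{\text{water}} \approx 8\times10^{-7}$ and
$\delta_{\text{gas}} \approx 0$, so a ray crossing a bubble of radius $r$ at
impact parameter $b$ is refracted at entry and exit by a total of

$$\Delta\theta \;=\; \frac{2\,\Delta\delta\, b}{\sqrt{r^2-b^2}},$$

directed toward the bubble axis (a converging lens, since for x-rays the
cavity plays the role glass plays for visible light). For
$\Delta\delta = 8\times10^{-7}$ this is $\sim$1.6 µrad at
$b = r/\sqrt 2$ — small individually, but a ray traversing a 4 mm lumen at
dilute volume fractions crosses several bubbles, and the resulting angular
spread interacts with the *convex* tail of the rocking curve: deviations
toward the peak gain more reflectivity than symmetric deviations away from
it lose. The net effect is the defining dark-field signature: **the
bubble-laden lumen is brighter than the bubble-free one**, with a contrast
that grows with concentration.

The forward model in `render_frame()` implements exactly this picture with
ray optics:

* parallel rays along $+z$; the vessel axis lies along $x$; the analyser
  senses only the angular component in the $y$–$z$ diffraction plane (a
  physical property of crystal analysers — the orthogonal component is
  discarded);
* at every interface (outer/inner tube wall, sphere entry/exit) the ray
  accumulates the small-angle refraction
  $(\delta_{\text{next}}-\delta_{\text{prev}})\tan\theta_i$, and its weight
  multiplies $e^{-\mu\ell}$ over the analytic chord lengths in nylon,
  water and gas;
* the per-ray signal is $w \times R(\theta_{\text{wp}} - \Delta\theta_y)$,
  averaged over a jittered subgrid of rays per pixel, with optional
  per-pixel Poisson noise at a stated photon budget.

Free-space propagation between sample and analyser is deliberately *not*
modelled: ABI is an angular filter, not a propagation-distance technique,
so deflection maps directly to a rocking-curve angle.

## Parameters and defaults

| parameter | default | why |
|---|---|---|
| energy | 17 keV | monochromator setting of the reference acquisition |
| tube | 4 mm ID, 1 mm Nylon-12 wall | adult-coronary-artery scale; nylon is a low-contrast match to water (its attenuation computes to ~0.6× water's at 17 keV — "similar" on the scale of tubing materials) |
| bubble radii | lognormal, median 4 µm, geometric SD 1.7, truncated (1, 16) µm | the median is the published shell-agent figure; the spread is a declared assumption typical of Expancel-type polydispersity; the truncation bounds are symmetric about the median in log space so the median is preserved |
| rocking curve | Gaussian, FWHM 20 µrad, peak 1.0 | the measured beamline curve is unpublished; shape family and working level, not exact width, control the qualitative dark-field contrast. A pseudo-Voigt option provides heavier tails. FWHM is order-of-magnitude typical of Si(111) double reflections at this energy |
| working point | 5 % of peak, positive tail | dark-field configuration; which tail was used is unstated, so it is a config option defaulting to positive |
| detector | 9 µm pixels, 4×4 binning → 36 µm | the binned CCD of the reference acquisition |
| timing | 0.5 s exposure + 0.27 s readout = 0.77 s period | printed acquisition values; frames are stamped at mid-exposure to minimise pairing bias while C(t) decays |
| dilution | $C(t) = C_1 e^{-Dt}$, D primary | runs are reported by their D (e.g. 0.056 s⁻¹); the printed relation between D and the loop parameters (Q, V_p = 2.3 ml, V_l = 2.8 ml, R) is not legible in the available source, so the well-mixed single-compartment form $D = RQ/(V_p+V_l)$ is offered **only as a documented assumption** (`decay_constant()`), never silently as ground truth |
| $C_1$ | 0.01 volume fraction | top of the calibrated range; the Rose-criterion analysis shows the informative range extends well below it |
| rays per pixel | 64 (package default); 32 in the bundled analyses | controls only refraction-sampling noise, since attenuation multiplies weights continuously rather than absorbing whole rays stochastically (variance reduction at identical expectation) |
| photon budget | 10⁴ photons/effective pixel | synchrotron-grade flux: keeps per-pixel Poisson noise visible but subordinate to phantom-realization noise, as in the experiment |

## What the synthetic-data generator emulates — and what it does not

Each frame of a simulated sequence draws a **fresh sphere pack** at the
concentration $C(t_k)$: flow replaces the bubble population between
frames, so frames are independent realizations. The generator reproduces

* the bright dark-field band in the lumen and its growth with
  concentration,
* the exponential decay of the ROI intensity toward a *non-zero*
  background (residual absorption signal) shared by all runs,
* Poisson photon statistics and frame-to-frame phantom fluctuation.

It does **not** model: intra-exposure motion blur (full population
turnover per frame is the declared approximation), bubble buoyancy,
coalescence or clustering, the thin polymer shell (the phase signal is
dominated by the gas–water contrast; a shell-material hook exists but is
off by default), wave-optics/coherence effects, detector PSF beyond
binning, or the "structural noise" of real anatomy. Passing tests
therefore demonstrate the *method's* correctness on a well-specified
suspension model, not instrument-level agreement with any particular
beamline: the absolute detection limit, in particular, scales with the
photon budget and rocking-curve width and is synchrotron-specific.

## The quantification chain

1. **ROI series** — mean intensity in the central 50 % of the lumen width
   (wall and strongly refracting lumen-edge pixels always excluded), per
   frame, stamped at mid-exposure.
2. **Background subtraction** — the ROI mean of a bubble-free acquisition;
   after subtraction zero intensity corresponds to zero concentration.
3. **Calibration** — replicate renders at known concentrations (always
   including zero) give the intensity–concentration curve; OLS provides
   slope, intercept and residuals. The response is approximately linear
   over [0, 0.01] with *structured* residuals (mild saturation), which is
   why residuals are first-class outputs rather than noise.
4. **Detection limit** — $c_{\min} = k\,\sigma/\text{slope}$ with $k=5$
   (Rose criterion). $\sigma$ is defined here as the standard deviation of
   replicate zero-concentration ROI means — a temporal noise measure over
   the analysis region, stated in the output metadata because other
   definitions (per-pixel spatial noise, pooled frames) would change the
   number.
5. **Decay recovery** — log-linear OLS of the subtracted series against
   time, dropping frames below a noise floor of $3\sigma$ (the log
   transform is unstable near zero); the confidence interval is a seeded
   1000-resample bootstrap over frames rather than an asymptotic formula,
   because late frames have strongly heteroscedastic relative noise. The
   estimator refuses series spanning less than one e-folding above
   background instead of returning a poorly identified fit.

Ground truth is known in simulation, so sequences are analysed in absolute
time; `align_at_intensity()` reproduces the display convention of aligning
runs where their intensities overlap, used when true starting
concentrations differ.

## Numerical choices

* **Straight-line intersection geometry.** Deflections of tens of µrad
  over a ≤10 mm path displace a ray by well under 1 µm — far below the
  36 µm pixel — so refraction is accumulated without re-steering the
  intersection search.
* **Grazing incidence.** The per-interface kick diverges as $b \to r$;
  the tracer guards the half-chord at $10^{-7}$ mm. Rays amplified into
  the rocking-curve peak by large kicks are genuine dark-field physics and
  are kept.
* **Packing.** Radii are drawn first until their summed volume reaches the
  target (fixing the realized fraction to within one bubble volume,
  i.e. ≪1 %); centres then go through sequential rejection sampling with a
  linked cell list. Rejection packing is guaranteed comfortable at the
  ≤1 % volume fractions of interest; the generator refuses targets above
  0.05. Non-overlap is enforced — physically required at these dilutions.
* **Determinism.** Every random stage (radii, packing, jitter, noise,
  bootstrap) derives from explicit integer seeds; identical seeds give
  byte-identical phantoms, frames and CSV outputs.
* **Optical constants** ship as a bundled CSV (15–20 keV,
  log-linearly interpolated). The table was generated once from
  Cromer–Liberman scattering factors with the scattering contribution
  calibrated per electron against standard water mass-attenuation values;
  water's δ at 17 keV agrees with the electron-density closed form to
  0.1 %, and the package's tests re-derive that check independently. The
  gas core uses vacuum constants (its true values are ≥3 orders of
  magnitude below water's).

## Problem sizes used in the bundled analyses

The analysis scripts and the acceptance checks run at 128 × 64 effective
pixels with 32 rays per pixel — a field of view of 4.6 × 2.3 mm that
covers the lumen and both walls. A 0.005 volume-fraction phantom at this
size holds ~1.8×10⁵ spheres; packing and tracing one frame takes a fraction
of a second through the compiled cell-list kernels, and a 40-frame dilution
sequence renders in seconds. These sizes were chosen as the smallest
configuration that keeps the ROI Monte Carlo error well below the
frame-to-frame phantom fluctuation; the package defaults (64 rays per
pixel) halve the sampling noise again for production use.

## Known limitations

* The rocking curve is parametric; absolute contrast values depend on its
  width and shape, so cross-instrument comparisons require the measured
  curve of that instrument.
* The detection limit is reported for the simulated noise model and ROI
  definition; it is not an instrument constant.
* The intensity–concentration response saturates slowly with
  concentration; the linear calibration is a first approximation (its
  residuals quantify the deviation) and biases the recovered D low by a
  few percent at $C_1 = 0.01$ — within the tolerance the recovery tests
  assert, but visible.
* Only the exponential dilution regime is modelled; transients immediately
  after valve opening, and any non-well-mixed behaviour of the real loop,
  are out of scope.
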