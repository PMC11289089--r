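---
title: "Segmented FCS on laser-scanning-microscope data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmented FCS on laser-scanning-microscope data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Fluorescence correlation spectroscopy (FCS) infers diffusion coefficients
and concentrations from the spontaneous intensity fluctuations produced by
fluorescent particles moving through a small observation volume. Inside
cells, a single long FCS record is fragile: organelles drift through the
focus, fluorophores photobleach, and the focus may sit across regions with
different mobility. Segmented FCS addresses this by cutting a long scan
record into many short temporal segments, computing one correlation
function per segment, selecting segments by their mean intensity (bright
nucleolus versus dimmer nucleoplasm, say), and averaging only the selected
curves. Each segment is normalized by its own mean, so slow trends — cell
motion, photobleaching — cancel instead of deforming the correlation curve.

`segfcs` implements this workflow for photon-count images exported from a
commercial confocal laser scanning microscope (LSM), which records either:

* **X-segmentation** — a slow raster or line scan along X. Fluctuations are
  resolved between consecutive pixels, so the lag clock is the pixel dwell
  time (microseconds). Suited to fast diffusion (solutions, GFP in cells).
  The scanner's motion contributes a known Gaussian factor to the curve.
* **Y-segmentation** — a fast line scan, with fluctuations resolved between
  successive passes over the same pixel column. The lag clock is the line
  period (milliseconds). Suited to slow dynamics (chromatin-binding
  proteins); the beam speed along the segmentation axis is zero.

Because exported TIFFs carry no usable acquisition metadata, timing and
geometry always travel in a sidecar configuration (`acq_meta()`,
`load_config()`) and are never read from TIFF tags.

## Correlation estimator

For a segment of `n_seg` pixels with intensities $I(k)$, the estimator is

$$\hat G(\xi) \;=\; \frac{\langle I(k)\,I(k+\xi)\rangle_T}
{\langle I(k)\rangle_T^2} - 1,$$

with averages restricted to the segment and products taken circularly
(periodic indexing) so that every lag is estimated from exactly `n_seg`
products; the numerator is evaluated by FFT and agrees with the direct
double sum to better than $10^{-10}$ relative error (a property checked
over random segments in the test suite). Lags are retained up to
`n_seg / 2`; beyond that, estimates from a duration-limited segment are
unreliable. The temporal axis is $\tau = \xi\,\delta t$ with $\delta t$ the
pixel time (X) or line time (Y).

When the detected photons are split over two detectors, the package
cross-correlates the channels (symmetrized over the two orderings).
Detector noise — shot noise, afterpulsing — is uncorrelated between the
channels, so the zero-lag spike present in an autocorrelation disappears;
accordingly fits include the zero lag for cross-correlations and exclude it
for autocorrelations.

Segments whose mean intensity is zero in any used channel are marked
invalid and excluded from averaging (with a logged count), never propagated
as NaN. The class average is the unweighted mean of the selected segments'
curves, with the standard error of the mean across segments attached.

## Segment maps and selection

The per-segment mean intensity (channels summed — selection should reflect
total signal) is arranged on a grid: scan lines × segments-per-line for
X-segmentation, time-segments × pixel columns for Y-segmentation. Each map
row — one scan line, or one time-segment spanning all columns — is divided
by its own maximum. This per-row normalization removes slow variation along
the orthogonal (time) axis, so photobleaching does not masquerade as a
spatial intensity feature; a fixture with a strong global exponential decay
normalizes to a flat map to within $10^{-12}$.

Selection is strictly intensity-based: explicit thresholds on the
normalized map (the default; no thresholds are hard-coded because sensible
values depend on the sample) or equal-quantile classes as a convenience.
Classes are disjoint; empty classes are reported, not dropped. Segments
adjacent to a region boundary are kept unless the user excludes them.
Trailing pixels that do not fill a segment are discarded so all segments
are identically sized and their curves exchangeable.

A rule of thumb guards segment length: the segment duration $T =
n_{seg}\,\delta t$ should exceed the diffusion time $\tau_D = w_0^2/(4D)$
by at least two orders of magnitude (`check_segment_duration()` warns
otherwise). Short-segment fit corrections are out of scope.

## Fit models

Averaged curves are fitted by bounded Levenberg–Marquardt least squares
(`minpack.lm`) to one of three nested models:

$$G(\tau) = G_0\,\frac{1}{1 + 4D\tau/w_0^2}
\;\underbrace{\exp\!\left(-\frac{(v\tau/w_0)^2}{1+4D\tau/w_0^2}\right)}_{\text{scanning}}
\;\underbrace{\left(1 + A_{tr} e^{-\tau/\tau_{tr}}\right)}_{\text{triplet}}$$

* `"diffusion"` — free 2D diffusion only (Y-segmentation: $v = 0$),
* `"diffusion_scan"` — adds the scanning factor (slow X scans),
* `"diffusion_scan_triplet"` — adds triplet blinking,
  $A_{tr} = f_{tr}/(1-f_{tr})$; enabled only on request, as triplet
  kinetics matter only for some fluorophores.

Units are fixed throughout: $\tau$ in s, $D$ in µm²/s, $w_0$ (the 1/e²
lateral spot radius) in µm, $v$ in µm/s. Following standard practice,
$w_0$ (from calibration against a reference dye of known $D$ —
`calibrate_w0()` fixes $D$ and frees $w_0$) and $v$ (from the acquisition
settings) stay fixed during sample fits; only $G_0$, $D$ and, when enabled,
the triplet terms are free. Fits are unweighted by default, with optional
$1/\mathrm{sem}^2$ weighting. Initialization: $G_0$ from the first three
fitted lags, $D$ from the half-decay lag, $A_{tr} = 0.5$ and
$\tau_{tr} = 5\ \mu s$ when freed. Non-convergence is reported as an error,
never silently replaced.

At 1 Hz line rate ($v = 15.4$ µm/s) the scanning factor deviates from 1 by
at most a few percent over ten diffusion times for cell-like $D$, which is
why Y-segmented and very slow X-segmented data are well described by the
pure diffusion model; the tests pin this deviation to its closed form.

### The baseline term

Normalizing each segment by its own finite-duration mean biases the
estimator by an approximately constant negative offset of order
$-(2/T)\int_0^{T} G\,\mathrm{d}t$. The offset is small against $G_0$ for
$T \gtrsim 100\,\tau_D$, but it dominates the curve's tail and, left
unmodelled, is absorbed as spuriously fast diffusion. The fit layer
therefore provides a constant baseline parameter (`offset`), fixed at 0 by
default and freed (`free = "offset"`) by the pipeline; this is the FCS
analogue of the baseline term routinely included in correlation fits, not a
change to the diffusion models. On simulated slow scans with
$T \approx 300\,\tau_D$, freeing the baseline reduces the bias of the
fitted $D$ from tens of percent to a few percent.

A second honest choice is the fit range. Unweighted fits that include very
long lags (where the model is near zero but the baseline is not) dilute the
information in the decay; the pipeline's parameter-recovery runs fit out to
roughly ten diffusion times. Both choices are plain function arguments.

Measured $D$ values convert to hydrodynamic radii via Stokes–Einstein,
$R_H = k_B T_{exp} / (6\pi\eta D)$, with defaults $T_{exp} = 293.15$ K
(20 °C) and $\eta = 0.001$ Pa·s.

## The simulator

`simulate_scan()` is a first-class forward model used to verify every
pipeline stage without instrument data. Point emitters perform independent
2D Brownian motion (per-step variance $2D\,\delta t$ per axis) in a
periodic box and are observed through a Gaussian profile
$\exp(-2r^2/w_0^2)$ centred on the instantaneous beam position; per-pixel
counts are Poisson draws on that intensity plus uncorrelated dark counts.
Details and the reasoning behind them:

* **2D, not 3D.** The fitted models are 2D Gaussian diffusion models, so
  the simulator matches them; axial structure would add parameters the
  analysis never estimates.
* **Scan motion.** In slow-raster mode the beam advances continuously at
  $v = \delta x/\delta t$ and positions are stepped every pixel dwell, with
  a single larger step over the retrace dead time between lines; when a
  dwell step would exceed $(w_0/5)^2$ in variance, dwells are subdivided
  automatically. In fast-line mode positions advance once per line period
  and each line samples fixed beam positions.
* **Two channels.** Photon splitting is implemented as Poisson thinning of
  the per-pixel intensity, exactly equivalent to an independent coin flip
  per photon: both channels share all correlated signal and none of the
  shot noise — precisely the property cross-correlation exploits.
* **Triplet blinking** is a two-state telegraph per emitter with
  equilibrium dark fraction $f_{tr}$ and correlation time $\tau_{tr}$;
  **photobleaching** is a single exponential permanent off-switch per
  emitter.
* **Regions.** Piecewise-constant regions along X carry their own $D$ and
  brightness. Particles are confined to their region by reflective walls —
  compartment physics; without confinement, region identity would wash out
  over the acquisition and the ground truth against which recovery is
  judged would be ill-defined. Homogeneous simulations use periodic
  minimum-image boundaries instead, with box sides at least $10\,w_0$ to
  keep periodic images of a particle from correlating with the beam.
* **Determinism.** A fixed seed reproduces the scan bit-for-bit; seeds are
  mandatory in tests.

Defaults mirror the instrument settings of the acquisitions the package is
designed around (3.05 µs pixels of 0.47 nm in slow-raster mode at 10 Hz;
presets for the 1 Hz slow line scan and the 1800 Hz fast line scan), with
$w_0 = 0.181$ µm. Counts-per-molecule and background have no instrument
reference, so brightness (0.3 counts per dwell per molecule at the beam
centre) and dark rate (0.02 counts per pixel per channel) were chosen once
as realistic photon-counting values with good test power.

What the simulator does **not** emulate — optical aberrations, resonant-
scanner velocity profiles, detector afterpulsing, 3D sectioning, cell
motion — bounds what passing tests show: they validate the estimator,
selection and fitting chain against the stated physical model, not
robustness to every instrument artifact.

## Verification at desk scale

The test suite regenerates all of its data. Problem sizes were chosen once
so the whole suite runs in minutes on one core:

* homogeneous slow-raster recovery: 8192-pixel lines × 64 lines (48 for
  the $D = 395$ µm²/s calibration dye, where dwell sub-stepping doubles the
  work), 200 particles in a 4 × 2 µm box; one line = one segment;
* two-region fast-line recovery: 64 columns × 8192 lines at 1800 Hz, 700
  particles in a 12.5 × 2 µm box, 1024-line segments, threshold selection
  at 0.5;
* bleaching robustness: the homogeneous run repeated with a bleach rate
  giving 50% signal loss over the acquisition, same seed.

Under those conditions the fitted $D$ of a $D = 100$ µm²/s scan lands
within 15% of truth, calibration recovers $w_0$ within 5%, the fitted
bright/dim $D$ ratio of the 30/10 µm²/s two-region scan falls in [2, 4],
and bleaching shifts the fitted $D$ by less than 15% — each asserted by
`tests/testthat/test-acceptance.R`, which is also where the closed-form
radius conversions and the scan timing arithmetic are pinned.

## Numerical and degenerate-input choices

* Circular (not zero-padded) correlation inside segments: all lags equally
  sampled; bias controlled by capping lags at `n_seg / 2`.
* Zero-mean segments: excluded and counted, never imputed.
* All-zero map rows: left at 0 and flagged; normalization is idempotent.
* Constant (particle-free) curves: fitting reports a fit error ("no
  positive correlation amplitude") rather than returning junk.
* Bidirectional scans: lines are independent segment sources for
  X-segmentation, so no de-interleaving is needed; Y-segmentation of
  bidirectional data would require reversing odd lines before column
  extraction, which the reader leaves to the user.
* Counts are stored as integers (16-bit TIFF round trip is exact below
  65536); analysis is floating point.
* The pixel time is taken verbatim from the configuration; where an
  instrument's nominal values disagree at the fourth digit (30.4 vs
  30.5 µs at 1 Hz), the tool does not arbitrate.

## Known limitations

* No short-segment fit correction: segments shorter than ~100 diffusion
  times produce distorted curves, and the package only warns.
* Selection is intensity-based only; no morphological segmentation.
* One diffusing component per fit; no anomalous diffusion, no 3D model
  with an axial term.
* Native instrument files (.lif) are not read; convert to TIFF first.
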