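# segfcs

Segmented fluorescence correlation spectroscopy (FCS) for photon-count
images from a commercial confocal laser scanning microscope (LSM).

FCS measures diffusion coefficients from the fluctuations of fluorescence
in a small observation volume. On a commercial LSM without a dedicated FCS
module, the raw material is a scan image: a slow raster/line scan along X
(fluctuations between consecutive pixels, µs resolution) or a fast line
scan (fluctuations between successive lines, ms resolution). Inside cells,
a single long record is corrupted by organelle motion, photobleaching and
regional heterogeneity. Segmented FCS cuts the record into short temporal
segments, computes one correlation function per segment,

G(ξ) = ⟨I(k) I(k+ξ)⟩_T / ⟨I(k)⟩_T² − 1,

selects segments on a per-line-normalized intensity map (e.g. nucleolus vs
nucleoplasm vs cytoplasm), and averages the selected curves,
G_av(τ) = ⟨G_j(τ)⟩. Because each segment is normalized by its own mean,
slow drifts cancel instead of deforming the curve. The averaged curve is
fitted like a single-point FCS measurement to

G(τ) = G₀ · 1/(1 + 4Dτ/w₀²) · exp(−(vτ/w₀)² / (1 + 4Dτ/w₀²)) · (1 + A_tr e^(−τ/τ_tr)),

with the scanning factor (speed v) used for slow X scans and the triplet
factor on request; w₀ is the 1/e² lateral spot radius, calibrated against
a reference dye of known D. Fitted D values convert to hydrodynamic radii
via Stokes–Einstein, R_H = k_B·T / (6πη·D).

The package is tidyverse-native: segment maps, correlation curves and fit
summaries are tibbles; fitted objects support `tidy()`, `glance()` and
`autoplot()`. A Brownian-dynamics simulator (`simulate_scan()`) generates
instrument-shaped synthetic acquisitions — Poisson counting, two-channel
splitting, dark counts, triplet blinking, photobleaching, piecewise
regions — so the entire pipeline is verifiable without a microscope.

## Worked example

Simulate a two-region fast line scan — a bright compartment with
D = 30 µm²/s occupying half the line, a dimmer one with D = 10 µm²/s —
then run the full segmented analysis:

```r
library(segfcs)

base <- sim_config(D = 10, n_particles = 700, scan_mode = "fast_x_linescan",
                   pixel_size = 194e-9, pixel_time = 3e-6,
                   line_frequency = 1800, n_px = 64, n_lines = 8192,
                   box = c(12.5, 2), brightness = 0.5, seed = 31)
cfg  <- make_two_region_config(base, split = 0.5, D_a = 30, D_b = 10,
                               brightness_ratio = 3)
scan <- simulate_scan(cfg)
scan
#> <scan_data> 8192 lines x 64 px, 2 channel(s), fast_x_linescan
#>   mean counts/pixel (all channels): 1.464

res <- analyze_scan(scan, n_seg = 1024, w0 = 0.181,
                    selection = list(thresholds = 0.5,
                                     labels = c("dim", "bright")))
glance(res)
#> # A tibble: 2 × 6
#>   class  n_segments     D  D_se    G0 reduced_chisq
#>   <chr>       <int> <dbl> <dbl> <dbl>         <dbl>
#> 1 dim           255  12.2 0.371 0.312    0.0000180
#> 2 bright        257  29.1 0.526 0.337    0.00000400
```

Y-segmentation cut each 8192-line column into 1024-line segments
(segment duration T = 0.57 s); thresholding the normalized segment
intensity map at 0.5 classified 512 segments into the two regions, and the
per-class averaged cross-correlation curves were fitted with the pure
diffusion model (the beam speed along the segmentation axis is zero). The
fitted coefficients, 29.1 and 12.2 µm²/s, recover the simulated 30 and
10 µm²/s; `G0` is the curve amplitude (inverse of the particles in focus)
and `reduced_chisq` the residual mean square of the fit.
`autoplot(res$curves$bright)` and `autoplot(res$fits$bright)` draw the
curve and the fit overlay; `res$map` is the segment intensity map.

Converting a solution measurement to a size:

```r
stokes_einstein_radius(106.4) * 1e9   # D in um^2/s -> radius in nm
#> [1] 2.02
```

— a ~2 nm hydrodynamic radius, GFP-sized.

A command-line wrapper with `simulate`, `analyze` and `calibrate`
subcommands is installed at `system.file("scripts", "segfcs",
package = "segfcs")`; all parameters live in YAML configs
(see `?load_config`, `?run_simulate`).

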