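Package: segfcs
Title: Segmented Fluorescence Correlation Spectroscopy for Laser Scanning
    Microscope Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts fluorescence correlation spectroscopy (FCS) data from
    raster-scan or line-scan photon-count images acquired on a commercial
    confocal laser scanning microscope. Scan records are divided into short
    temporal segments along the fast (X) or slow (Y) axis, a correlation
    function is computed per segment by FFT, segments are selected on a
    per-line-normalized intensity map, and the averaged curves are fitted to
    diffusion models with optional scanning and triplet terms to obtain
    diffusion coefficients in distinct subcellular regions. Includes a
    Brownian-dynamics scan simulator with Poisson photon counting, two-channel
    splitting, triplet blinking, photobleaching and piecewise-constant spatial
    regions, so the whole pipeline is verifiable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
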