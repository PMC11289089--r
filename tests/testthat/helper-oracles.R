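# Independent direct double-sum oracle for the circular correlation
# estimator: G(xi) = <I(k) I(k+xi)>_T / <I(k)>_T^2 - 1 with periodic
# indexing, computed without FFTs.
acf_direct <- function(x, max_lag, x2 = NULL) {
  n <- length(x)
  sapply(0:max_lag, function(xi) {
    idx <- ((seq_len(n) - 1L + xi) %% n) + 1L
    if (is.null(x2)) {
      mean(x * x[idx]) / mean(x)^2 - 1
    } else {
      (mean(x * x2[idx]) + mean(x2 * x[idx])) / 2 /
        (mean(x) * mean(x2)) - 1
    }
  })
}

# metadata used by most fixtures: the slow bidirectional raster settings
# (10 Hz line rate, 3.05 us pixel dwell, 0.47 nm pixels)
solution_meta <- function(n_channels = 1L) {
  acq_meta(pixel_time = 3.05e-6, pixel_size = 0.47e-9,
           scan_mode = "slow_x_raster", line_frequency = 10,
           n_channels = n_channels)
}

# a small scan with known integer counts
toy_scan <- function(counts, n_channels = 1L, meta = NULL) {
  meta <- meta %||% solution_meta(n_channels)
  if (n_channels == 1L) scan_data(counts, meta)
  else scan_data(rep(list(counts), n_channels), meta)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# background-corrected amplitude expectation for a homogeneous simulation:
# G(0) = 1 / (density * pi * w0^2), reduced by the squared signal contrast
# (S / (S + B))^2 when uncorrelated dark counts are present.
expected_G0 <- function(cfg) {
  dens <- cfg$n_particles / prod(cfg$box)
  n_focal <- dens * pi * cfg$w0^2
  signal <- dens * cfg$brightness * pi * cfg$w0^2 / 2
  n_ch <- cfg$meta$n_channels
  contrast <- signal / (signal + n_ch * cfg$dark_rate)
  (1 / n_focal) * contrast^2
}
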