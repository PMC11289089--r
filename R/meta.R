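#' Acquisition metadata for a scan record
#'
#' Exported TIFFs carry no timing information, so the acquisition parameters
#' travel in a sidecar object (usually loaded from a config file with
#' [load_config()]). All times are seconds, all lengths metres.
#'
#' The lag clock of the downstream correlation analysis is `pixel_time` for
#' X-segmentation (fluctuations between consecutive pixels of a line) and
#' `line_time` for Y-segmentation (fluctuations between consecutive lines).
#'
#' @param pixel_time Seconds the scanner dwells on one pixel. Must be > 0.
#' @param pixel_size Metres per pixel along the fast (X) axis. Must be > 0.
#' @param scan_mode `"slow_x_raster"` (slow scanning along X, fluctuations
#'   resolved pixel-to-pixel) or `"fast_x_linescan"` (fast line scanning,
#'   fluctuations resolved line-to-line).
#' @param line_time Seconds per line (the full line period, including any
#'   retrace dead time). If missing it is derived as `1 / line_frequency`.
#' @param line_frequency Line scanning frequency in Hz (informational when
#'   `line_time` is given; checked for consistency within 1%).
#' @param bidirectional Logical; was the scanner recording during retrace?
#' @param n_channels Number of detection channels (>= 1).
#'
#' @return An object of class `acq_meta` (a named list).
#' @examples
#' meta <- acq_meta(pixel_time = 3.05e-6, pixel_size = 0.47e-9,
#'                  scan_mode = "slow_x_raster", line_frequency = 10)
#' meta$line_time # 0.1 s
#' scan_speed(meta) * 1e6 # ~154 um/s
#' @export
acq_meta <- function(pixel_time, pixel_size,
                     scan_mode = c("slow_x_raster", "fast_x_linescan"),
                     line_time = NULL, line_frequency = NULL,
                     bidirectional = FALSE, n_channels = 1L) {
  scan_mode <- match.arg(scan_mode)
  if (!is.numeric(pixel_time) || length(pixel_time) != 1 || pixel_time <= 0) {
    stop_validation("`pixel_time` must be a single positive number (seconds).")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0) {
    stop_validation("`pixel_size` must be a single positive number (metres).")
  }
  if (is.null(line_time)) {
    if (is.null(line_frequency)) {
      stop_validation("Provide `line_time` or `line_frequency`.")
    }
    if (line_frequency <= 0) stop_validation("`line_frequency` must be > 0.")
    line_time <- 1 / line_frequency
  } else {
    if (!is.numeric(line_time) || length(line_time) != 1 || line_time <= 0) {
      stop_validation("`line_time` must be a single positive number (seconds).")
    }
    if (!is.null(line_frequency)) {
      if (abs(line_time - 1 / line_frequency) > 0.01 * line_time) {
        warn(sprintf(
          "line_time (%.4g s) and 1/line_frequency (%.4g s) disagree by more than 1%%.",
          line_time, 1 / line_frequency))
      }
    }
  }
  if (line_time < pixel_time) {
    stop_validation("`line_time` must be at least `pixel_time`.")
  }
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 1L) {
    stop_validation("`n_channels` must be an integer >= 1.")
  }
  structure(
    list(pixel_time = pixel_time, line_time = line_time,
         pixel_size = pixel_size, scan_mode = scan_mode,
         bidirectional = isTRUE(bidirectional), n_channels = n_channels,
         line_frequency = line_frequency %||% (1 / line_time)),
    class = "acq_meta")
}

#' @export
print.acq_meta <- function(x, ...) {
  cat("<acq_meta>\n")
  cat(sprintf("  scan_mode:     %s%s\n", x$scan_mode,
              if (x$bidirectional) " (bidirectional)" else ""))
  cat(sprintf("  pixel_time:    %.4g us\n", x$pixel_time * 1e6))
  cat(sprintf("  line_time:     %.4g ms (%.4g Hz)\n",
              x$line_time * 1e3, 1 / x$line_time))
  cat(sprintf("  pixel_size:    %.4g nm\n", x$pixel_size * 1e9))
  cat(sprintf("  scan speed:    %.4g um/s\n", scan_speed(x) * 1e6))
  cat(sprintf("  channels:      %d\n", x$n_channels))
  invisible(x)
}

#' Quantities derived from acquisition metadata
#'
#' Timing and geometry arithmetic of a scan: the active duration of one line
#' `T_line = N_px * pixel_time`, its physical length `L_line = N_px *
#' pixel_size`, the total experiment duration `T_exp = N_lines * line_time`,
#' and the scan speed `v = pixel_size / pixel_time`.
#'
#' @param meta An [acq_meta()] object.
#' @param n_px Pixels per line.
#' @param n_lines Number of lines acquired.
#' @return A number: seconds ([line_duration()], [experiment_duration()]),
#'   metres ([line_length()]) or metres/second ([scan_speed()]).
#' @examples
#' m <- acq_meta(30.5e-6, 0.47e-9, "slow_x_raster", line_frequency = 1)
#' line_duration(m, 8192) # 0.25 s
#' @export
line_duration <- function(meta, n_px) n_px * meta$pixel_time

#' @rdname line_duration
#' @export
line_length <- function(meta, n_px) n_px * meta$pixel_size

#' @rdname line_duration
#' @export
experiment_duration <- function(meta, n_lines) n_lines * meta$line_time

#' @rdname line_duration
#' @export
scan_speed <- function(meta) meta$pixel_size / meta$pixel_time

#' Expected particle number in an observation volume
#'
#' FCS needs few particles in focus: e.g. 0.1 uM in a 1 fL volume is about
#' 60 particles, which sets the typical working concentration range.
#'
#' @param concentration Molar concentration (mol/L).
#' @param volume_l Observation volume in litres (1 fL = 1e-15 L).
#' @return Expected number of particles.
#' @examples
#' particles_in_volume(0.1e-6, 1e-15) # ~60
#' @export
particles_in_volume <- function(concentration, volume_l) {
  if (concentration < 0 || volume_l <= 0) {
    stop_validation("concentration must be >= 0 and volume_l > 0.")
  }
  avogadro <- 6.02214076e23
  concentration * avogadro * volume_l
}
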