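#' Photon-count scan record
#'
#' Container for a 2D photon-count record plus its acquisition metadata.
#' The axis convention is fixed: rows are lines (the slow axis), columns are
#' pixels within a line (the fast axis), for both XY raster and XT line-scan
#' data. Counts are stored as integers; analysis is done in floating point.
#'
#' @param counts An integer matrix `(n_lines x n_px)`, or a list of such
#'   matrices (one per channel).
#' @param meta An [acq_meta()] object; its `n_channels` must match `counts`.
#' @return An object of class `scan_data` with elements `channels` (list of
#'   integer matrices), `meta`, `n_px`, `n_lines`.
#' @examples
#' m <- acq_meta(1e-5, 1e-7, "fast_x_linescan", line_time = 1e-3)
#' sd <- scan_data(matrix(0L, nrow = 100, ncol = 32), m)
#' sd$n_px
#' @export
scan_data <- function(counts, meta) {
  if (!inherits(meta, "acq_meta")) stop_validation("`meta` must be an acq_meta object.")
  if (is.matrix(counts)) counts <- list(counts)
  if (!is.list(counts) || !all(vapply(counts, is.matrix, logical(1)))) {
    stop_validation("`counts` must be a matrix or list of matrices.")
  }
  if (length(counts) != meta$n_channels) {
    stop_validation(sprintf(
      "channel count mismatch: data has %d channel(s), meta declares %d.",
      length(counts), meta$n_channels))
  }
  dims <- lapply(counts, dim)
  if (length(unique(lapply(dims, identity))) != 1) {
    stop_validation("per-channel arrays must share an identical shape.")
  }
  counts <- lapply(counts, check_integer_counts)
  structure(
    list(channels = counts, meta = meta,
         n_px = ncol(counts[[1]]), n_lines = nrow(counts[[1]])),
    class = "scan_data")
}

# losslessly coerce to integer; warn+round only within 1e-6 of integers
check_integer_counts <- function(m) {
  if (is.integer(m)) {
    if (any(m < 0L)) stop_validation("counts must be non-negative.")
    return(m)
  }
  r <- round(m)
  dev <- max(abs(m - r))
  if (dev > 1e-6) {
    stop_validation(sprintf(
      "pixel data are not integer-valued (max deviation %.3g).", dev))
  }
  if (dev > 0) warn("non-integer pixel data within 1e-6 of integers; rounding.")
  if (any(r < 0)) stop_validation("counts must be non-negative.")
  storage.mode(r) <- "integer"
  r
}

#' @export
print.scan_data <- function(x, ...) {
  cat(sprintf("<scan_data> %d lines x %d px, %d channel(s), %s\n",
              x$n_lines, x$n_px, length(x$channels), x$meta$scan_mode))
  tot <- Reduce(`+`, lapply(x$channels, function(m) as.numeric(sum(m))))
  cat(sprintf("  mean counts/pixel (all channels): %.4g\n",
              tot / (x$n_px * x$n_lines)))
  invisible(x)
}

# channel-summed counts as a double matrix
summed_counts <- function(scan) {
  out <- matrix(0, scan$n_lines, scan$n_px)
  for (ch in scan$channels) out <- out + ch
  out
}
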