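#' Build the segment grid for a scan
#'
#' Divides the scan record into contiguous, non-overlapping temporal segments
#' of exactly `n_seg` pixels along the chosen axis. For `axis = "x"` each
#' scan line yields `floor(n_px / n_seg)` segments of duration
#' `T = n_seg * pixel_time`; for `axis = "y"` each pixel column yields
#' `floor(n_lines / n_seg)` segments of duration `T = n_seg * line_time`.
#' A trailing remainder shorter than `n_seg` is discarded so that all
#' segments are identically sized and their correlation curves exchangeable.
#'
#' @param scan A [scan_data()] object.
#' @param axis `"x"` or `"y"`, the segmentation axis.
#' @param n_seg Pixels per segment (integer > 1, at most the axis extent).
#' @return A tibble with one row per segment: `seg_id`, `row` (normalization
#'   group: scan line for axis `"x"`, time-segment index for axis `"y"`),
#'   `col` (segment index along the line for `"x"`, pixel column for `"y"`),
#'   `px_start`, `px_end` (1-based index range along the segmentation axis).
#'   Attributes `axis`, `n_seg`, `n_px`, `n_lines` describe the grid.
#' @examples
#' m <- acq_meta(30.5e-6, 0.47e-9, "slow_x_raster", line_frequency = 1)
#' s <- scan_data(matrix(1L, 4, 8192), m)
#' g <- segment_grid(s, "x", 1024)   # 8 segments per line
#' nrow(g) # 32
#' @export
segment_grid <- function(scan, axis = c("x", "y"), n_seg) {
  axis <- match.arg(axis)
  n_seg <- as.integer(n_seg)
  extent <- if (axis == "x") scan$n_px else scan$n_lines
  if (is.na(n_seg) || n_seg < 2L) stop_validation("`n_seg` must be an integer > 1.")
  if (n_seg > extent) {
    stop_validation(sprintf(
      "n_seg (%d) exceeds the %s-axis extent (%d).", n_seg, axis, extent))
  }
  k <- extent %/% n_seg
  starts <- (seq_len(k) - 1L) * n_seg + 1L
  if (axis == "x") {
    grid <- tidyr::expand_grid(row = seq_len(scan$n_lines), col = seq_len(k))
    grid$px_start <- starts[grid$col]
  } else {
    # row (time-segment) varies fastest, matching the column order in which
    # segment series are extracted (down each pixel column)
    grid <- tidyr::expand_grid(col = seq_len(scan$n_px), row = seq_len(k))
    grid <- grid[, c("row", "col")]
    grid$px_start <- starts[grid$row]
  }
  grid$px_end <- grid$px_start + n_seg - 1L
  grid <- dplyr::mutate(grid, seg_id = dplyr::row_number(), .before = 1)
  attr(grid, "axis") <- axis
  attr(grid, "n_seg") <- n_seg
  attr(grid, "n_px") <- scan$n_px
  attr(grid, "n_lines") <- scan$n_lines
  grid
}

#' Per-segment mean intensity map
#'
#' Computes the arithmetic mean of the photon counts in each segment
#' (channels summed, so selection reflects total signal) and arranges the
#' values on a grid: `(lines x segments-per-line)` for X-segmentation,
#' `(time-segments x columns)` for Y-segmentation. Use [normalize_map()] to
#' add the per-row normalized values used for segment selection.
#'
#' @inheritParams segment_grid
#' @param grid Optional precomputed [segment_grid()]; built if missing.
#' @return A `segment_map` tibble: `seg_id`, `row`, `col`, `px_start`,
#'   `px_end`, `raw_mean`, `norm_mean` (NA until normalized), `all_zero`.
#' @export
segment_map <- function(scan, axis = c("x", "y"), n_seg, grid = NULL) {
  axis <- match.arg(axis)
  if (is.null(grid)) grid <- segment_grid(scan, axis, n_seg)
  n_seg <- attr(grid, "n_seg")
  counts <- summed_counts(scan)
  segs <- segment_series(counts, axis, n_seg)   # n_seg x n_segments matrix
  raw <- colMeans(segs)
  # segment_series emits columns in grid order (see ordering note there)
  map <- grid
  map$raw_mean <- raw
  map$norm_mean <- NA_real_
  map$all_zero <- raw == 0
  if (any(map$all_zero)) {
    inform(sprintf("%d all-zero segment(s) flagged.", sum(map$all_zero)))
  }
  class(map) <- c("segment_map", class(tibble()))
  for (a in c("axis", "n_seg", "n_px", "n_lines")) attr(map, a) <- attr(grid, a)
  map
}

# Cut a counts matrix (n_lines x n_px) into an (n_seg x n_segments) matrix of
# segment series. Column order: for axis "x", line-major (line 1 segments
# 1..k, line 2 segments 1..k, ...) = grid order (row, col) with col fastest;
# for axis "y", column-major (column 1 time-segments 1..k, ...) = grid order
# with row fastest. Both match tidyr::expand_grid ordering in segment_grid.
segment_series <- function(counts, axis, n_seg) {
  if (axis == "x") {
    k <- ncol(counts) %/% n_seg
    use <- t(counts[, seq_len(k * n_seg), drop = FALSE])
    matrix(as.numeric(use), nrow = n_seg)
  } else {
    k <- nrow(counts) %/% n_seg
    use <- counts[seq_len(k * n_seg), , drop = FALSE]
    matrix(as.numeric(use), nrow = n_seg)
  }
}

# map a (row, col) pair in grid order to the column index of segment_series
series_index <- function(map) {
  axis <- attr(map, "axis")
  if (axis == "x") {
    k <- max(map$col)
    (map$row - 1L) * k + map$col
  } else {
    k <- max(map$row)
    (map$col - 1L) * k + map$row
  }
}

#' Normalize a segment map per line
#'
#' Each map row (one scan line for X-segmentation; one time-segment spanning
#' all columns for Y-segmentation) is divided by its own maximum, correcting
#' slow variations along Y or T (e.g. photobleaching) and highlighting only
#' relative intensity variations along X. All-zero rows stay at 0 and are
#' flagged. The operation is idempotent.
#'
#' @param map A [segment_map()] tibble.
#' @return The map with `norm_mean` filled in (maximum of each non-zero row
#'   is exactly 1).
#' @examples
#' # a row with raw means 10, 20, 40, 40 normalizes to 0.25, 0.5, 1, 1
#' @export
normalize_map <- function(map) {
  src <- if (all(is.na(map$norm_mean))) map$raw_mean else map$norm_mean
  mx <- tapply(src, map$row, max)
  denom <- as.numeric(mx[as.character(map$row)])
  zero_rows <- denom == 0
  denom[zero_rows] <- 1
  map$norm_mean <- src / denom
  if (any(zero_rows)) {
    inform(sprintf("%d all-zero normalization row(s) left at 0.",
                   length(unique(map$row[zero_rows]))))
  }
  map
}

#' Select segments by intensity class
#'
#' Classifies segments on the normalized intensity map, either by explicit
#' thresholds (e.g. low < 0.4 <= mid < 0.8 <= high, mirroring
#' nucleolus/nucleoplasm/cytoplasm selection) or by `n_classes`
#' equal-quantile bins. Classes are disjoint by construction; empty classes
#' are reported with a warning, never silently dropped. All-zero segments
#' are left unclassified (`NA`).
#'
#' @param map A normalized [segment_map()] (see [normalize_map()]).
#' @param thresholds Strictly increasing cut points in (0, 1) on `norm_mean`.
#' @param labels Class labels, `length(thresholds) + 1` of them, ordered from
#'   dimmest to brightest. Defaults to `low`/`mid`/`high`-style names.
#' @param n_classes Alternative to `thresholds`: number of equal-quantile
#'   classes.
#' @return The map tibble with a `class` factor column added.
#' @export
select_segments <- function(map, thresholds = NULL, labels = NULL,
                            n_classes = NULL) {
  if (all(is.na(map$norm_mean))) {
    stop_validation("map is not normalized; call normalize_map() first.")
  }
  ok <- !map$all_zero
  if (is.null(thresholds)) {
    if (is.null(n_classes)) stop_validation("give `thresholds` or `n_classes`.")
    if (n_classes < 2) stop_validation("`n_classes` must be >= 2.")
    thresholds <- quantile(map$norm_mean[ok],
                           probs = seq_len(n_classes - 1) / n_classes,
                           names = FALSE, type = 7)
    thresholds <- unique(thresholds)
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop_validation("`thresholds` must be strictly increasing.")
  }
  if (is.null(labels)) {
    labels <- switch(as.character(length(thresholds) + 1),
                     "2" = c("low", "high"),
                     "3" = c("low", "mid", "high"),
                     paste0("class", seq_len(length(thresholds) + 1)))
  }
  if (length(labels) != length(thresholds) + 1) {
    stop_validation("`labels` must have length(thresholds) + 1 entries.")
  }
  cls <- cut(map$norm_mean, breaks = c(-Inf, thresholds, Inf),
             labels = labels, right = FALSE)
  cls[!ok] <- NA
  empty <- setdiff(labels, unique(as.character(cls[!is.na(cls)])))
  if (length(empty)) {
    warn(paste0("empty selection class(es): ", paste(empty, collapse = ", ")))
  }
  map$class <- cls
  attr(map, "thresholds") <- thresholds
  map
}

#' Check that a segment is long enough for the expected dynamics
#'
#' A segment of duration `T` only samples fluctuations reliably when `T` is
#' at least two orders of magnitude longer than the characteristic diffusion
#' time `tau_D = w0^2 / (4 D)`; shorter segments distort the correlation
#' curve and need dedicated corrections that are out of scope here.
#'
#' @param T_segment Segment duration in seconds.
#' @param tau_d Expected correlation time in seconds.
#' @return `TRUE` (ok) or `FALSE` (too short), invisibly; warns when
#'   `T_segment < 100 * tau_d`.
#' @examples
#' check_segment_duration(25e-3, 77e-6) # ok
#' @export
check_segment_duration <- function(T_segment, tau_d) {
  if (T_segment <= 0 || tau_d <= 0) {
    stop_validation("durations must be positive.")
  }
  ok <- T_segment >= 100 * tau_d
  if (!ok) {
    warn(sprintf(
      "segment duration %.3g s is less than 100x the correlation time %.3g s; the correlation curve may be distorted.",
      T_segment, tau_d))
  }
  invisible(ok)
}
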