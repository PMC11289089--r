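# constructor for a correlation-curve tibble
new_fcs_acf <- function(lag_px, G, sem = 0, n_segments = 1L, tau_s = NA_real_,
                        mode = "auto", delta_t = NA_real_, label = NULL) {
  out <- tibble(lag_px = as.integer(lag_px), tau_s = tau_s, G = G,
                sem = sem, n_segments = as.integer(n_segments))
  class(out) <- c("fcs_acf", class(tibble()))
  attr(out, "mode") <- mode
  attr(out, "delta_t") <- delta_t
  attr(out, "label") <- label
  out
}

#' Correlation function of one segment
#'
#' Computes the normalized correlation of a segment's intensity sequence,
#' `G(xi) = <I(k) I(k+xi)>_T / <I(k)>_T^2 - 1`, with the averages restricted
#' to the segment's own pixels. Products are circular (periodic) within the
#' segment and the numerator is evaluated by FFT; the estimate is identical
#' to the direct double-sum definition to floating-point precision. In
#' `"cross"` mode two simultaneously detected channels are correlated,
#' `<I1(k) I2(k+xi)> / (<I1><I2>) - 1`, symmetrized as the mean of the +xi
#' and -xi estimates; this removes detector noise (which is uncorrelated
#' between channels) from the zero-lag region.
#'
#' Normalizing by the segment's own mean is what makes segmented analysis
#' robust to slow trends such as photobleaching: each segment is its own
#' reference, and no detrending is applied within a segment.
#'
#' @param x Numeric vector: the segment's intensity sequence (channel 1 in
#'   cross mode).
#' @param x2 Channel-2 sequence for `mode = "cross"`.
#' @param mode `"auto"` or `"cross"`.
#' @param max_lag Largest lag retained, at most `length(x) / 2` (the default):
#'   longer lags of a duration-limited segment are unreliable.
#' @param delta_t Seconds per lag step (pixel time for X-segmentation, line
#'   time for Y-segmentation); if given, the temporal lag axis is filled in.
#' @return An `fcs_acf` tibble with columns `lag_px`, `tau_s`, `G`, `sem`
#'   (0 for a single segment), `n_segments`.
#' @examples
#' acf_segment(c(2, 0, 2, 0))$G # 1, -1, 1
#' @export
acf_segment <- function(x, x2 = NULL, mode = c("auto", "cross"),
                        max_lag = NULL, delta_t = NA_real_) {
  mode <- match.arg(mode)
  n <- length(x)
  if (n < 2) stop_validation("segment must have at least 2 pixels.")
  max_lag <- max_lag %||% (n %/% 2L)
  if (max_lag > n %/% 2L) {
    stop_validation("max_lag must not exceed half the segment length.")
  }
  if (mode == "cross") {
    if (is.null(x2) || length(x2) != n) {
      stop_validation("cross mode needs a second channel of equal length.")
    }
    if (mean(x) <= 0 || mean(x2) <= 0) {
      stop_validation("zero-mean segment: no signal to correlate.")
    }
    G <- cross_corr_fft(x, x2)
  } else {
    if (mean(x) <= 0) stop_validation("zero-mean segment: no signal to correlate.")
    G <- auto_corr_fft(x)
  }
  lag <- 0:max_lag
  new_fcs_acf(lag, G[lag + 1L], sem = 0, n_segments = 1L,
              tau_s = lag * delta_t, mode = mode, delta_t = delta_t)
}

# circular autocorrelation G(xi) for all lags, via FFT
auto_corr_fft <- function(x) {
  n <- length(x)
  f <- fft(x)
  num <- Re(fft(f * Conj(f), inverse = TRUE)) / n^2   # <x(k) x(k+xi)>
  num / mean(x)^2 - 1
}

# symmetrized circular cross-correlation: mean of both channel orderings
cross_corr_fft <- function(x1, x2) {
  n <- length(x1)
  f1 <- fft(x1); f2 <- fft(x2)
  c12 <- Re(fft(f1 * Conj(f2), inverse = TRUE)) / n^2
  c21 <- Re(fft(f2 * Conj(f1), inverse = TRUE)) / n^2
  (c12 + c21) / 2 / (mean(x1) * mean(x2)) - 1
}

#' Correlation functions for every segment of a scan
#'
#' Cuts the scan into segments along the chosen axis and computes one
#' correlation curve per segment (FFT, circular within the segment; see
#' [acf_segment()]). Segments with zero mean intensity in any used channel
#' are marked invalid and excluded from averaging rather than propagating
#' NaNs. In `"auto"` mode channels are summed before correlating.
#'
#' @inheritParams segment_grid
#' @param mode `"auto"` or `"cross"` (cross requires a two-channel scan).
#' @param max_lag Largest lag retained (default `n_seg / 2`).
#' @return A `segment_acfs` object: list with `lag_px`, `G` (matrix, one
#'   column per segment in [segment_grid()] order), `index` (tibble `seg_id`,
#'   `row`, `col`, `valid`), `mode`, `axis`, `n_seg`, `delta_t`.
#' @export
scan_acfs <- function(scan, axis = c("x", "y"), n_seg,
                      mode = c("auto", "cross"), max_lag = NULL) {
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  grid <- segment_grid(scan, axis, n_seg)
  n_seg <- attr(grid, "n_seg")
  max_lag <- max_lag %||% (n_seg %/% 2L)
  if (max_lag > n_seg %/% 2L) {
    stop_validation("max_lag must not exceed n_seg / 2.")
  }
  delta_t <- if (axis == "x") scan$meta$pixel_time else scan$meta$line_time
  if (mode == "cross") {
    if (length(scan$channels) < 2L) {
      stop_validation("cross mode requires a two-channel scan.")
    }
    s1 <- segment_series(scan$channels[[1]], axis, n_seg)
    s2 <- segment_series(scan$channels[[2]], axis, n_seg)
    m1 <- colMeans(s1); m2 <- colMeans(s2)
    valid <- m1 > 0 & m2 > 0
    G <- matrix(NA_real_, max_lag + 1L, ncol(s1))
    if (any(valid)) {
      f1 <- mvfft(s1[, valid, drop = FALSE])
      f2 <- mvfft(s2[, valid, drop = FALSE])
      c12 <- Re(mvfft(f1 * Conj(f2), inverse = TRUE)) / n_seg^2
      c21 <- Re(mvfft(f2 * Conj(f1), inverse = TRUE)) / n_seg^2
      num <- (c12 + c21) / 2
      Gv <- sweep(num, 2, m1[valid] * m2[valid], `/`) - 1
      G[, valid] <- Gv[seq_len(max_lag + 1L), , drop = FALSE]
    }
  } else {
    s <- segment_series(summed_counts(scan), axis, n_seg)
    m <- colMeans(s)
    valid <- m > 0
    G <- matrix(NA_real_, max_lag + 1L, ncol(s))
    if (any(valid)) {
      f <- mvfft(s[, valid, drop = FALSE])
      num <- Re(mvfft(f * Conj(f), inverse = TRUE)) / n_seg^2
      Gv <- sweep(num, 2, m[valid]^2, `/`) - 1
      G[, valid] <- Gv[seq_len(max_lag + 1L), , drop = FALSE]
    }
  }
  if (any(!valid)) {
    inform(sprintf("%d zero-mean segment(s) excluded from correlation.",
                   sum(!valid)))
  }
  index <- tibble(seg_id = grid$seg_id, row = grid$row, col = grid$col,
                  valid = valid)
  structure(list(lag_px = 0:max_lag, G = G, index = index, mode = mode,
                 axis = axis, n_seg = n_seg, delta_t = delta_t),
            class = "segment_acfs")
}

#' @export
print.segment_acfs <- function(x, ...) {
  cat(sprintf("<segment_acfs> %d segments (%d valid), %s mode, lags 0..%d, dt = %.4g s\n",
              ncol(x$G), sum(x$index$valid), x$mode, max(x$lag_px), x$delta_t))
  invisible(x)
}

#' Convert a spatial correlation curve to a temporal one
#'
#' Fills in the temporal lag axis `tau = xi * delta_t`, where `delta_t` is
#' the pixel time for X-segmentation or the line time for Y-segmentation.
#' Correlation amplitudes are unchanged.
#'
#' @param curve An `fcs_acf` tibble.
#' @param delta_t Seconds per lag step.
#' @return The curve with `tau_s` set.
#' @export
to_temporal <- function(curve, delta_t) {
  if (is.null(delta_t) || !is.finite(delta_t) || delta_t <= 0) {
    stop_validation("`delta_t` must be a positive number of seconds.")
  }
  curve$tau_s <- curve$lag_px * delta_t
  attr(curve, "delta_t") <- delta_t
  curve
}

#' Average the correlation curves of selected segments
#'
#' Computes the unweighted per-lag mean of the curves of all (valid)
#' segments in a selection class, with the standard error of the mean across
#' segments. This averaged curve is then fitted like a single-point FCS
#' measurement.
#'
#' @param sacfs A [scan_acfs()] result.
#' @param selection Optional classified [segment_map()] (see
#'   [select_segments()]); if `NULL`, all valid segments are averaged.
#' @param class Class label to average (required when `selection` has
#'   classes).
#' @return An `fcs_acf` tibble with `sem` and `n_segments` filled in.
#' @export
average_acfs <- function(sacfs, selection = NULL, class = NULL) {
  keep <- sacfs$index$valid
  if (!is.null(selection)) {
    if (is.null(class)) stop_validation("give the `class` label to average.")
    if (!"class" %in% names(selection)) {
      stop_validation("`selection` has no class column; run select_segments().")
    }
    sel_ids <- paste(selection$row, selection$col)[
      !is.na(selection$class) & selection$class == class]
    keep <- keep & paste(sacfs$index$row, sacfs$index$col) %in% sel_ids
  }
  n <- sum(keep)
  if (n == 0) {
    stop_validation("no valid segments in the selection to average.")
  }
  Gm <- sacfs$G[, keep, drop = FALSE]
  gav <- rowMeans(Gm)
  sem <- if (n > 1) apply(Gm, 1, sd) / sqrt(n) else rep(0, nrow(Gm))
  new_fcs_acf(sacfs$lag_px, gav, sem = sem, n_segments = n,
              tau_s = sacfs$lag_px * sacfs$delta_t, mode = sacfs$mode,
              delta_t = sacfs$delta_t, label = class)
}
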