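#' Read a photon-count TIFF exported from a laser scanning microscope
#'
#' Reads single- or multi-page TIFFs as saved by ImageJ from instrument files.
#' Because exported TIFFs drop acquisition metadata, timing and geometry are
#' supplied explicitly via `meta` (usually from [load_config()]), never
#' inferred from TIFF tags. Multi-channel data are accepted either as
#' separate pages or as a sample-interleaved page and normalized internally
#' to one matrix per channel.
#'
#' @param path Path to a TIFF file.
#' @param meta An [acq_meta()] object describing the acquisition.
#' @return A [scan_data()] object.
#' @export
read_scan_tiff <- function(path, meta) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  channels <- list()
  for (pg in pages) {
    if (length(dim(pg)) == 3L) {
      # sample-interleaved page: third dimension holds channels
      channels <- c(channels, lapply(seq_len(dim(pg)[3]), function(k) pg[, , k]))
    } else {
      channels <- c(channels, list(pg))
    }
  }
  if (length(channels) != meta$n_channels) {
    stop_validation(sprintf(
      "channel count mismatch: TIFF resolves to %d channel(s), meta declares %d.",
      length(channels), meta$n_channels))
  }
  scan_data(channels, meta)
}

#' Write a scan record to TIFF
#'
#' Counts are stored as 16-bit grey pages (one per channel), so the
#' write/read round trip preserves counts exactly for values below 65536.
#'
#' @param scan A [scan_data()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scan_tiff <- function(scan, path) {
  mx <- max(vapply(scan$channels, max, numeric(1)))
  if (mx > 65535) stop_validation("counts exceed the 16-bit TIFF range.")
  pages <- lapply(scan$channels, function(m) m / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Load acquisition metadata and analysis parameters from a config file
#'
#' The configuration is a YAML `key: value` file with acquisition keys
#' (`pixel_time_s`, `line_time_s` and/or `line_frequency_hz`, `pixel_size_m`,
#' `scan_mode`, `bidirectional`, `n_channels`) and optional analysis keys
#' (`segment_axis`, `n_seg`, `selection`, `fit_model`, `fit_range_s`,
#' `max_lag`, `w0_um`, `triplet`). Defaults: one channel, monodirectional,
#' axis `"x"`, correlation mode `"cross"` when two channels are present and
#' `"auto"` otherwise, triplet fitting disabled.
#'
#' @param path Path to a YAML config file.
#' @return A list with elements `meta` (an [acq_meta()]) and `analysis`
#'   (a named list of analysis parameters).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_validation(sprintf("config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  need <- c("pixel_size_m", "scan_mode")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    stop_validation(paste0("config is missing required key(s): ",
                           paste(miss, collapse = ", ")))
  }
  if (is.null(cfg$pixel_time_s)) {
    stop_validation("config is missing required key: pixel_time_s")
  }
  meta <- acq_meta(
    pixel_time = as.numeric(cfg$pixel_time_s),
    pixel_size = as.numeric(cfg$pixel_size_m),
    scan_mode = cfg$scan_mode,
    line_time = if (!is.null(cfg$line_time_s)) as.numeric(cfg$line_time_s),
    line_frequency = if (!is.null(cfg$line_frequency_hz)) as.numeric(cfg$line_frequency_hz),
    bidirectional = isTRUE(cfg$bidirectional),
    n_channels = cfg$n_channels %||% 1L)
  axis <- cfg$segment_axis %||%
    if (meta$scan_mode == "fast_x_linescan") "y" else "x"
  # YAML 1.1 reads a bare y as boolean TRUE
  if (isTRUE(axis)) axis <- "y"
  if (!is.character(axis) || !axis %in% c("x", "y")) {
    stop_validation("segment_axis must be \"x\" or \"y\".")
  }
  analysis <- list(
    segment_axis = axis,
    n_seg = if (!is.null(cfg$n_seg)) as.integer(cfg$n_seg),
    selection = cfg$selection,
    fit_model = cfg$fit_model %||% NULL,
    fit_range_s = if (!is.null(cfg$fit_range_s)) as.numeric(cfg$fit_range_s),
    max_lag = if (!is.null(cfg$max_lag)) as.integer(cfg$max_lag),
    w0_um = if (!is.null(cfg$w0_um)) as.numeric(cfg$w0_um),
    triplet = isTRUE(cfg$triplet),
    mode = cfg$mode %||% if (meta$n_channels >= 2L) "cross" else "auto")
  if (!is.null(analysis$n_seg) && analysis$n_seg <= 1L) {
    stop_validation("n_seg must be an integer > 1.")
  }
  list(meta = meta, analysis = analysis)
}

#' Export correlation curves to CSV
#'
#' Writes one or more curves as a single long-format CSV with columns
#' `lag_px`, `tau_s`, `G`, `sem`, `n_segments`, `label`. Values round-trip
#' through [read_acf_table()] exactly.
#'
#' @param curves A single `fcs_acf` tibble or a (possibly named) list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_acf_table <- function(curves, path) {
  if (inherits(curves, "fcs_acf")) curves <- list(curves)
  if (length(curves) == 0) stop_validation("no curves to write.")
  labs <- names(curves) %||% rep("", length(curves))
  labs[labs == ""] <- paste0("curve", seq_along(curves))[labs == ""]
  tab <- purrr::map2_dfr(curves, labs, function(cv, lb) {
    tibble(lag_px = cv$lag_px, tau_s = cv$tau_s, G = cv$G,
           sem = cv$sem, n_segments = cv$n_segments, label = lb)
  })
  readr::write_csv(tab, path)
  invisible(path)
}

#' @rdname write_acf_table
#' @return [read_acf_table()] returns a named list of `fcs_acf` tibbles.
#' @export
read_acf_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  split(tab, tab$label) |>
    purrr::map(function(d) {
      new_fcs_acf(d$lag_px, d$G, sem = d$sem, n_segments = d$n_segments[1],
                  tau_s = d$tau_s, label = d$label[1])
    })
}

#' Write a fit report as JSON
#'
#' @param fit An `fcs_fit` object (or a named list of them).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  as_report <- function(f) {
    co <- tidy(f)
    list(model = f$model,
         parameters = setNames(as.list(co$estimate), co$term),
         std_errors = setNames(as.list(co$std.error), co$term),
         fixed = f$fixed,
         reduced_chisq = f$reduced_chisq,
         n_segments = f$n_segments,
         fit_range_s = f$fit_range,
         converged = f$converged)
  }
  rep <- if (inherits(fit, "fcs_fit")) as_report(fit) else lapply(fit, as_report)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Export a segment intensity map
#'
#' Writes the per-segment mean-intensity map either as CSV (long format) or
#' as a float TIFF image for visual inspection.
#'
#' @param map A [segment_map()] tibble.
#' @param path Output path.
#' @param what `"norm"` (default) or `"raw"` values for the TIFF export.
#' @return `path`, invisibly.
#' @export
write_segment_map_csv <- function(map, path) {
  readr::write_csv(as_tibble(map), path)
  invisible(path)
}

#' @rdname write_segment_map_csv
#' @export
write_segment_map_tiff <- function(map, path, what = c("norm", "raw")) {
  what <- match.arg(what)
  v <- if (what == "norm") map$norm_mean else map$raw_mean
  if (all(is.na(v))) stop_validation("map has no values to export.")
  img <- matrix(0, max(map$row), max(map$col))
  img[cbind(map$row, map$col)] <- v
  if (what == "raw" && max(img) > 0) img <- img / max(img)
  tiff::writeTIFF(img, path, bits.per.sample = 32L, compression = "none")
  invisible(path)
}
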