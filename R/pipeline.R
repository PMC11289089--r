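#' Run the full segmented-FCS analysis on a scan
#'
#' Orchestrates the pipeline: segment the scan, build and normalize the
#' intensity map, classify segments by intensity, compute per-segment
#' correlation curves, average each class, and fit each averaged curve to a
#' diffusion model. Defaults follow the acquisition mode: X-segmentation
#' fits diffusion-with-scanning using the scan speed from the metadata;
#' Y-segmentation fits pure diffusion (the speed along Y is zero).
#'
#' @param scan A [scan_data()] object.
#' @param axis Segmentation axis, `"x"` or `"y"` (default by scan mode:
#'   `"x"` for slow rasters, `"y"` for fast line scans).
#' @param n_seg Pixels per segment.
#' @param w0 Calibrated observation-spot radius, um.
#' @param mode Correlation mode; default `"cross"` for two-channel scans.
#' @param selection `list(thresholds =, labels =)` or `list(n_classes =)`;
#'   `NULL` analyzes all segments as a single class `"all"`.
#' @param model Fit model; default `"diffusion_scan"` for axis `"x"`,
#'   `"diffusion"` for axis `"y"`.
#' @param max_lag,fit_range,weights Passed to [scan_acfs()] / [fit_acf()].
#' @param baseline Logical (default `TRUE`): free a constant baseline term
#'   in each fit to absorb the small negative offset of segment-normalized
#'   correlation estimates (see [fit_acf()]).
#' @param tau_d_hint Optional expected correlation time (s); when given, the
#'   segment duration is checked against the 100x rule
#'   ([check_segment_duration()]).
#' @return An `fcs_analysis` object: list with `map` (classified segment
#'   map), `acfs`, `curves` (named list of averaged `fcs_acf`), `fits`
#'   (named list of `fcs_fit`), `log` (per-stage counts).
#' @export
analyze_scan <- function(scan, n_seg, w0, axis = NULL, mode = NULL,
                         selection = NULL, model = NULL, max_lag = NULL,
                         fit_range = NULL, weights = "none", baseline = TRUE,
                         tau_d_hint = NULL) {
  axis <- axis %||%
    if (scan$meta$scan_mode == "fast_x_linescan") "y" else "x"
  mode <- mode %||% if (length(scan$channels) >= 2L) "cross" else "auto"
  model <- model %||% if (axis == "x") "diffusion_scan" else "diffusion"
  v <- if (axis == "x") scan_speed(scan$meta) * 1e6 else 0

  delta_t <- if (axis == "x") scan$meta$pixel_time else scan$meta$line_time
  if (!is.null(tau_d_hint)) {
    check_segment_duration(n_seg * delta_t, tau_d_hint)
  }

  grid <- segment_grid(scan, axis, n_seg)
  map <- segment_map(scan, axis, n_seg, grid = grid)
  map <- normalize_map(map)
  if (!is.null(selection)) {
    map <- select_segments(map, thresholds = selection$thresholds,
                           labels = selection$labels,
                           n_classes = selection$n_classes)
    classes <- levels(map$class)
  } else {
    map$class <- factor(ifelse(map$all_zero, NA, "all"))
    classes <- "all"
  }
  sacfs <- scan_acfs(scan, axis, n_seg, mode = mode, max_lag = max_lag)

  curves <- list(); fits <- list()
  for (cl in classes) {
    n_in_class <- sum(!is.na(map$class) & map$class == cl)
    if (n_in_class == 0) {
      warn(sprintf("class '%s' is empty; skipped.", cl))
      next
    }
    cv <- average_acfs(sacfs, map, cl)
    curves[[cl]] <- cv
    fits[[cl]] <- tryCatch(
      fit_acf(cv, model = model, w0 = w0, v = v, fit_range = fit_range,
              weights = weights,
              free = if (baseline) "offset" else NULL),
      segfcs_fit_error = function(e) {
        warn(sprintf("fit failed for class '%s': %s", cl, conditionMessage(e)))
        NULL
      })
  }
  structure(
    list(map = map, acfs = sacfs, curves = curves, fits = fits,
         model = model, axis = axis,
         log = list(n_segments = nrow(map),
                    n_excluded = sum(!sacfs$index$valid),
                    n_per_class = vapply(curves, function(cv)
                      cv$n_segments[1], integer(1)))),
    class = "fcs_analysis")
}

#' @export
print.fcs_analysis <- function(x, ...) {
  cat(sprintf("<fcs_analysis> %s-segmentation, %d segments (%d excluded)\n",
              toupper(x$axis), x$log$n_segments, x$log$n_excluded))
  print(tidy(x))
  invisible(x)
}

#' Tidy a full segmented-FCS analysis
#'
#' @param x An `fcs_analysis` from [analyze_scan()].
#' @param ... Unused.
#' @return A tibble with one row per intensity class and fitted parameter
#'   (long format): `class`, `n_segments`, `term`, `estimate`, `std.error`,
#'   `fixed`.
#' @export
tidy.fcs_analysis <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(f, cl) {
    if (is.null(f)) return(tibble())
    dplyr::mutate(tidy(f), class = cl,
                  n_segments = f$n_segments, .before = 1)
  })
}

#' @rdname tidy.fcs_analysis
#' @return [glance.fcs_analysis()] returns one row per class with the
#'   fitted diffusion coefficient and amplitude.
#' @export
glance.fcs_analysis <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(f, cl) {
    if (is.null(f)) return(tibble())
    tibble(class = cl, n_segments = f$n_segments,
           D = f$estimate[["D"]], D_se = f$std_error["D"] %||% NA_real_,
           G0 = f$estimate[["G0"]], reduced_chisq = f$reduced_chisq)
  })
}

# --- command-style entry points (used by the installed CLI script) -----------

#' Pipeline commands
#'
#' Thin orchestration layer used by the `segfcs` command-line script
#' (installed under `inst/scripts`): each command reads a YAML config,
#' runs the corresponding package functions and writes its outputs (TIFF,
#' CSV curve tables, JSON fit reports, a JSON run manifest) to `outdir`.
#'
#' @param config Path to a YAML config file. For [run_simulate()] the file
#'   holds [sim_config()] fields under a `sim:` key; for the others it is a
#'   [load_config()] acquisition/analysis config.
#' @param outdir Output directory (created if missing).
#' @param input Path to a scan TIFF.
#' @param seed Optional integer overriding the config seed.
#' @param D_ref Reference diffusion coefficient (um^2/s) for calibration.
#' @return The main result of the command, invisibly ([run_simulate()]: the
#'   simulated [scan_data()]; [run_analyze()]: the `fcs_analysis`;
#'   [run_calibrate()]: the calibration `fcs_fit`).
#' @export
run_simulate <- function(config, outdir, seed = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  raw <- yaml::read_yaml(config)
  args <- raw$sim %||% raw
  if (!is.null(args$regions)) args$regions <- dplyr::bind_rows(args$regions)
  if (!is.null(seed)) args$seed <- as.integer(seed)
  preset <- args$preset; args$preset <- NULL
  cfg <- if (!is.null(preset)) do.call(sim_preset, c(list(preset = preset), args))
         else do.call(sim_config, args)
  scan <- simulate_scan(cfg)
  tif <- file.path(outdir, "simulated_scan.tif")
  write_scan_tiff(scan, tif)
  sidecar <- file.path(outdir, "simulated_scan_config.yml")
  m <- scan$meta
  yaml::write_yaml(list(
    pixel_time_s = m$pixel_time, line_time_s = m$line_time,
    line_frequency_hz = m$line_frequency, pixel_size_m = m$pixel_size,
    scan_mode = m$scan_mode, bidirectional = m$bidirectional,
    n_channels = m$n_channels), sidecar)
  write_manifest(outdir, "simulate", config,
                 list(tiff = tif, sidecar = sidecar), seed = cfg$seed)
  invisible(scan)
}

#' @rdname run_simulate
#' @export
run_analyze <- function(input, config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg <- load_config(config)
  a <- cfg$analysis
  if (is.null(a$n_seg)) stop_validation("config must set n_seg for analysis.")
  if (is.null(a$w0_um)) stop_validation("config must set w0_um for fitting.")
  scan <- read_scan_tiff(input, cfg$meta)
  model <- a$fit_model %||%
    if (a$segment_axis == "x") {
      if (isTRUE(a$triplet)) "diffusion_scan_triplet" else "diffusion_scan"
    } else "diffusion"
  res <- analyze_scan(scan, n_seg = a$n_seg, w0 = a$w0_um,
                      axis = a$segment_axis, mode = a$mode,
                      selection = a$selection, model = model,
                      max_lag = a$max_lag, fit_range = a$fit_range_s)
  write_acf_table(res$curves, file.path(outdir, "acf_curves.csv"))
  write_segment_map_csv(res$map, file.path(outdir, "segment_map.csv"))
  write_segment_map_tiff(res$map, file.path(outdir, "segment_map.tif"))
  fits <- purrr::compact(res$fits)
  if (length(fits)) write_fit_report(fits, file.path(outdir, "fit_report.json"))
  jsonlite::write_json(res$log, file.path(outdir, "stage_log.json"),
                       auto_unbox = TRUE)
  write_manifest(outdir, "analyze", config,
                 list(input = input, curves = "acf_curves.csv",
                      fits = "fit_report.json"),
                 extra = list(axis = res$axis, n_seg = a$n_seg,
                              model = model))
  invisible(res)
}

#' @rdname run_simulate
#' @export
run_calibrate <- function(input, config, D_ref, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (missing(D_ref) || is.null(D_ref)) {
    stop_validation("calibration requires D_ref (um^2/s).")
  }
  cfg <- load_config(config)
  a <- cfg$analysis
  scan <- read_scan_tiff(input, cfg$meta)
  axis <- a$segment_axis
  n_seg <- a$n_seg %||% scan$n_px
  sacfs <- scan_acfs(scan, axis, n_seg, mode = a$mode, max_lag = a$max_lag)
  cv <- average_acfs(sacfs)
  v <- if (axis == "x") scan_speed(scan$meta) * 1e6 else 0
  fit <- calibrate_w0(cv, D_ref = as.numeric(D_ref), v = v,
                      free = "offset", fit_range = a$fit_range_s)
  out <- list(w0_um = fit$estimate[["w0"]],
              w0_se_um = unname(fit$std_error["w0"]),
              D_ref = as.numeric(D_ref),
              reduced_chisq = fit$reduced_chisq,
              n_segments = fit$n_segments)
  jsonlite::write_json(out, file.path(outdir, "calibration.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(outdir, "calibrate", config,
                 list(input = input, report = "calibration.json"))
  invisible(fit)
}

# run manifest: enough to reproduce all deterministic outputs
write_manifest <- function(outdir, command, config, files, seed = NULL,
                           extra = NULL) {
  man <- c(list(command = command, config = normalizePath(config),
                outputs = files, seed = seed,
                tool = paste0("segfcs ",
                              as.character(utils::packageVersion("segfcs"))),
                timestamp = format(Sys.time(), tz = "UTC")),
           extra)
  jsonlite::write_json(man, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(NULL)
}
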