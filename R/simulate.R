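#' Configuration for a synthetic scan acquisition
#'
#' Describes a full synthetic acquisition: point emitters performing 2D
#' Brownian diffusion in a periodic box, observed through a Gaussian
#' detection profile `exp(-2 r^2 / w0^2)` centred on the instantaneous scan
#' position, with Poisson photon counting, optional two-channel splitting,
#' uncorrelated dark counts, triplet blinking, exponential photobleaching
#' and piecewise-constant spatial regions differing in `D` and brightness.
#'
#' Defaults reproduce the slow bidirectional raster conditions used for
#' solution measurements on a Leica SP8-class instrument: 10 Hz line
#' frequency, 3.05 us pixel time, 0.47 nm pixel size, 8192-pixel lines,
#' `w0 = 0.181` um. Presets adjust them for the two cell acquisition modes.
#'
#' @param D Diffusion coefficient, um^2/s (per-region values come from
#'   `regions`).
#' @param n_particles Number of emitters in the box.
#' @param brightness Mean detected counts per pixel dwell per particle at
#'   the beam centre (all channels combined).
#' @param w0 1/e^2 lateral radius of the detection profile, um.
#' @param box Length-2 numeric, periodic box size in um (X, Y). Each side
#'   must be at least `10 * w0` to guard against periodic self-correlation,
#'   and the X side must cover the scanned line.
#' @param scan_mode `"slow_x_raster"` (diffusion stepped every pixel dwell)
#'   or `"fast_x_linescan"` (positions sampled once per line).
#' @param pixel_size,pixel_time,line_time,line_frequency,n_px,n_lines,bidirectional
#'   Scan geometry and timing, as in [acq_meta()].
#' @param n_channels 1 or 2 detection channels.
#' @param channel_split Probability that a photon lands in channel 1
#'   (two-channel case). Splitting is Poisson thinning — exactly equivalent
#'   to an independent coin flip per photon — so the channels share all
#'   correlated signal but none of the shot noise.
#' @param dark_rate Mean uncorrelated dark counts per pixel per channel.
#' @param triplet Optional `list(f_tr =, tau_tr =)`: dark-state fraction and
#'   correlation time (s) of a two-state telegraph each emitter follows.
#' @param bleach_rate Per-second rate of irreversible off-switching (0 = no
#'   bleaching).
#' @param regions Optional tibble/data.frame with columns `x_start`, `x_end`
#'   (um), `D`, `brightness_scale`: piecewise-constant regions along X.
#'   Particles are confined to their region (reflective walls), which keeps
#'   region identity meaningful over the acquisition, as for molecules in a
#'   subcellular compartment.
#' @param substeps Diffusion sub-steps per dwell in slow mode; `NULL` picks
#'   `ceiling(2 D dt / (w0/5)^2)` so a single step stays well below the
#'   spot size.
#' @param seed Integer seed; a fixed seed reproduces the scan bit-for-bit.
#' @param preset Optional starting point: `"solution_xy"` (slow raster, as
#'   the defaults), `"gfp_xt"` (slow line scan at 1 Hz, 30.5 us pixel time)
#'   or `"parp1_xt"` (fast line scan at 1800 Hz, 194 nm pixels).
#' @param ... Overrides applied on top of the preset.
#' @return A validated `sim_config` object (named list).
#' @export
sim_config <- function(D = 100, n_particles = 200, brightness = 0.3,
                       w0 = 0.181, box = NULL,
                       scan_mode = c("slow_x_raster", "fast_x_linescan"),
                       pixel_size = 0.47e-9, pixel_time = 3.05e-6,
                       line_time = NULL, line_frequency = 10,
                       n_px = 8192, n_lines = 128, bidirectional = FALSE,
                       n_channels = 2, channel_split = 0.5, dark_rate = 0.02,
                       triplet = NULL, bleach_rate = 0, regions = NULL,
                       substeps = NULL, seed = 1) {
  scan_mode <- match.arg(scan_mode)
  meta <- acq_meta(pixel_time, pixel_size, scan_mode, line_time,
                   line_frequency, bidirectional, n_channels)
  line_len_um <- n_px * pixel_size * 1e6
  if (is.null(box)) box <- c(max(line_len_um, 10 * w0), max(2, 10 * w0))
  box <- as.numeric(unlist(box))   # YAML sequences may arrive as lists
  if (length(box) == 1) box <- c(box, box)
  if (length(box) != 2 || any(!is.finite(box))) {
    stop_validation("`box` must be one or two positive numbers (um).")
  }
  if (any(box < 10 * w0)) {
    stop_validation("each box side must be at least 10 * w0.")
  }
  if (box[1] < line_len_um - 1e-9) {
    stop_validation("box X side must cover the scanned line length.")
  }
  if (n_particles < 0 || brightness < 0 || dark_rate < 0 || bleach_rate < 0) {
    stop_validation("particle number, brightness and rates must be >= 0.")
  }
  if (channel_split <= 0 || channel_split >= 1) {
    if (n_channels == 2) stop_validation("channel_split must be in (0, 1).")
  }
  if (!is.null(triplet)) {
    if (is.null(triplet$f_tr) || is.null(triplet$tau_tr) ||
        triplet$f_tr <= 0 || triplet$f_tr >= 1 || triplet$tau_tr <= 0) {
      stop_validation("triplet needs f_tr in (0,1) and tau_tr > 0.")
    }
  }
  if (!is.null(regions)) {
    regions <- as_tibble(regions)
    need <- c("x_start", "x_end", "D", "brightness_scale")
    if (!all(need %in% names(regions))) {
      stop_validation("regions needs columns x_start, x_end, D, brightness_scale.")
    }
    if (any(regions$x_end <= regions$x_start)) {
      stop_validation("each region must have x_end > x_start.")
    }
  }
  if (meta$line_time < n_px * pixel_time - 1e-12 &&
      scan_mode == "slow_x_raster") {
    stop_validation("line_time shorter than n_px * pixel_time.")
  }
  structure(
    list(D = D, n_particles = as.integer(n_particles),
         brightness = brightness, w0 = w0, box = box, meta = meta,
         n_px = as.integer(n_px), n_lines = as.integer(n_lines),
         channel_split = channel_split, dark_rate = dark_rate,
         triplet = triplet, bleach_rate = bleach_rate, regions = regions,
         substeps = substeps, seed = as.integer(seed)),
    class = "sim_config")
}

#' @rdname sim_config
#' @export
sim_preset <- function(preset = c("solution_xy", "gfp_xt", "parp1_xt"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    solution_xy = list(scan_mode = "slow_x_raster", pixel_size = 0.47e-9,
                       pixel_time = 3.05e-6, line_frequency = 10,
                       n_px = 8192, n_lines = 128, bidirectional = TRUE),
    gfp_xt = list(scan_mode = "slow_x_raster", pixel_size = 0.47e-9,
                  pixel_time = 30.5e-6, line_frequency = 1,
                  n_px = 8192, n_lines = 128, bidirectional = TRUE, D = 29),
    parp1_xt = list(scan_mode = "fast_x_linescan", pixel_size = 194e-9,
                    pixel_time = 3e-6, line_frequency = 1800,
                    n_px = 128, n_lines = 204800, D = 1.3))
  do.call(sim_config, modifyList(args, list(...)))
}

#' Two-region variant of a simulation config
#'
#' Splits the scanned line into two piecewise-constant regions (an
#' intensity-contrast scenario such as nucleolus vs nucleoplasm): region A
#' covers the first `split` fraction of the box with diffusion coefficient
#' `D_a` and relative brightness `brightness_ratio`; region B covers the
#' rest with `D_b` and brightness 1.
#'
#' @param base A [sim_config()].
#' @param split Fraction of the box X side in region A (0 < split < 1).
#' @param D_a,D_b Diffusion coefficients of the two regions, um^2/s.
#' @param brightness_ratio Brightness of region A relative to region B.
#' @return A `sim_config` with `regions` set.
#' @export
make_two_region_config <- function(base, split = 0.5, D_a, D_b,
                                   brightness_ratio = 3) {
  if (!inherits(base, "sim_config")) stop_validation("`base` must be a sim_config.")
  if (split <= 0 || split >= 1) stop_validation("`split` must be in (0, 1).")
  bx <- base$box[1]
  base$regions <- tibble(
    x_start = c(0, split * bx), x_end = c(split * bx, bx),
    D = c(D_a, D_b), brightness_scale = c(brightness_ratio, 1))
  base
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %s, %d x %d px, %d particles, D = %s um^2/s\n",
              x$meta$scan_mode, x$n_lines, x$n_px, x$n_particles,
              if (is.null(x$regions)) format(x$D)
              else paste(format(x$regions$D), collapse = "/")))
  invisible(x)
}

#' Simulate a scan acquisition
#'
#' Runs the Brownian-dynamics forward model described in [sim_config()] and
#' returns a photon-count record shaped exactly like an instrument export.
#' In slow-raster mode particle positions advance every pixel dwell (with
#' automatic sub-stepping when a single step would be large relative to the
#' spot) and the beam moves along X at `v = pixel_size / pixel_time`,
#' jumping over the retrace dead time between lines. In fast-line mode
#' positions advance once per line and the line's pixels sample fixed beam
#' positions.
#'
#' @param config A [sim_config()] object.
#' @return A [scan_data()] with matching [acq_meta()].
#' @export
simulate_scan <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_validation("`config` must be a sim_config object.")
  }
  withr::with_seed(config$seed, {
    mu <- if (config$meta$scan_mode == "slow_x_raster") {
      sim_intensity_slow(config)
    } else {
      sim_intensity_fast(config)
    }
    counts_from_intensity(mu, config)
  })
}

# --- internals ---------------------------------------------------------------

# particle initial positions, per-particle D / brightness / confinement
init_particles <- function(cfg) {
  np <- cfg$n_particles
  x0 <- runif(np, 0, cfg$box[1])
  y0 <- runif(np, -cfg$box[2] / 2, cfg$box[2] / 2)
  if (is.null(cfg$regions)) {
    list(x0 = x0, y0 = y0, D = rep(cfg$D, np),
         eps = rep(cfg$brightness, np),
         lo = rep(NA_real_, np), hi = rep(NA_real_, np))
  } else {
    ri <- findInterval(x0, c(cfg$regions$x_start[1], cfg$regions$x_end))
    ri[ri < 1] <- 1L
    ri[ri > nrow(cfg$regions)] <- nrow(cfg$regions)
    list(x0 = x0, y0 = y0, D = cfg$regions$D[ri],
         eps = cfg$brightness * cfg$regions$brightness_scale[ri],
         lo = cfg$regions$x_start[ri], hi = cfg$regions$x_end[ri])
  }
}

# fold a free trajectory into [lo, hi] (reflective walls)
reflect_fold <- function(x, lo, hi) {
  L <- hi - lo
  z <- (x - lo) %% (2 * L)
  lo + ifelse(z <= L, z, 2 * L - z)
}

# minimum-image displacement on a periodic axis
wrap_min_image <- function(dx, L) dx - L * round(dx / L)

# telegraph emission state (1 bright / 0 dark) sampled at times t (sorted)
telegraph_state <- function(t, f_tr, tau_tr, t_total) {
  k_dark <- f_tr / tau_tr      # bright -> dark
  k_bright <- (1 - f_tr) / tau_tr
  state0 <- runif(1) >= f_tr   # start from equilibrium occupancy
  mean_cycle <- 1 / k_dark + 1 / k_bright
  n_guess <- max(16L, ceiling(2.5 * t_total / mean_cycle))
  dw <- numeric(0)
  total <- 0
  while (total < t_total) {
    # dwell j (0-based) is in the initial state when j is even
    n_new <- n_guess
    dw_new <- numeric(n_new)
    idx <- seq_len(n_new)
    start_par <- length(dw) %% 2L
    is_bright <- ((idx - 1L + start_par) %% 2L == 0L) == state0
    dw_new[is_bright] <- rexp(sum(is_bright), k_dark)
    dw_new[!is_bright] <- rexp(sum(!is_bright), k_bright)
    dw <- c(dw, dw_new)
    total <- sum(dw)
  }
  edges <- cumsum(dw)
  seg <- findInterval(t, edges)           # 0-based segment index
  bright_seg <- (seg %% 2L == 0L) == state0
  as.numeric(bright_seg)
}

# per-particle emission gate: telegraph * bleaching, at absolute times t
emission_gate <- function(t, cfg, t_total) {
  gate <- NULL
  if (!is.null(cfg$triplet)) {
    gate <- telegraph_state(t, cfg$triplet$f_tr, cfg$triplet$tau_tr, t_total)
  }
  if (cfg$bleach_rate > 0) {
    t_b <- rexp(1, cfg$bleach_rate)
    alive <- as.numeric(t < t_b)
    gate <- if (is.null(gate)) alive else gate * alive
  }
  gate
}

sim_intensity_slow <- function(cfg) {
  m <- cfg$meta
  n_px <- cfg$n_px; n_lines <- cfg$n_lines
  dt <- m$pixel_time
  gap <- m$line_time - n_px * dt
  px_um <- m$pixel_size * 1e6
  maxD <- if (is.null(cfg$regions)) cfg$D else max(cfg$regions$D)
  nsub <- cfg$substeps %||% max(1L, ceiling(2 * maxD * dt / (cfg$w0 / 5)^2))
  dt_f <- dt / nsub
  n_fine_line <- n_px * nsub
  n_fine <- n_lines * n_fine_line

  # beam X position at each fine step of one line (dwell subdivided)
  beam_line <- (seq_len(n_fine_line) - 0.5) * px_um / nsub
  beam_x <- rep(beam_line, n_lines)
  if (m$bidirectional) {
    odd <- rep(seq_len(n_lines) %% 2L == 0L, each = n_fine_line)
    beam_x[odd] <- rep(rev(beam_line), n_lines)[odd]
  }
  # absolute time of each fine step (line period includes retrace dead time)
  t_line0 <- rep((seq_len(n_lines) - 1L) * m$line_time, each = n_fine_line)
  t_fine <- t_line0 + rep((seq_len(n_fine_line) - 0.5) * dt_f, n_lines)
  t_total <- n_lines * m$line_time

  # index pattern to drop the inter-line gap step from cumulated trajectories
  per_line <- n_fine_line + 1L
  keep_idx <- rep(seq_len(n_fine_line), n_lines) +
    rep((seq_len(n_lines) - 1L) * per_line, each = n_fine_line)

  pp <- init_particles(cfg)
  inv_w2 <- 2 / cfg$w0^2
  mu <- numeric(n_fine)
  sd_gap_base <- sqrt(2 * pmax(gap, 0))
  for (i in seq_len(cfg$n_particles)) {
    sd_step <- sqrt(2 * pp$D[i] * dt_f)
    sd_gap <- sd_gap_base * sqrt(pp$D[i])
    sds <- rep(c(rep(sd_step, n_fine_line), sd_gap), n_lines)
    xs <- cumsum(rnorm(length(sds), 0, sds))
    ys <- cumsum(rnorm(length(sds), 0, sds))
    x <- pp$x0[i] + xs[keep_idx]
    y <- pp$y0[i] + ys[keep_idx]
    dx <- if (is.na(pp$lo[i])) {
      wrap_min_image(x - beam_x, cfg$box[1])
    } else {
      reflect_fold(x, pp$lo[i], pp$hi[i]) - beam_x
    }
    dy <- wrap_min_image(y, cfg$box[2])
    g <- pp$eps[i] * exp(-inv_w2 * (dx * dx + dy * dy))
    gate <- emission_gate(t_fine, cfg, t_total)
    if (!is.null(gate)) g <- g * gate
    mu <- mu + g
  }
  if (nsub > 1L) {
    mu <- colMeans(matrix(mu, nrow = nsub))
  }
  # vector ordered (line, pixel) with pixel fastest
  matrix(mu, nrow = n_lines, byrow = TRUE)
}

sim_intensity_fast <- function(cfg) {
  m <- cfg$meta
  n_px <- cfg$n_px; n_lines <- cfg$n_lines
  lt <- m$line_time
  px_um <- m$pixel_size * 1e6
  beam_x <- (seq_len(n_px) - 0.5) * px_um
  t_lines <- (seq_len(n_lines) - 1L) * lt
  t_total <- n_lines * lt
  pp <- init_particles(cfg)
  inv_w2 <- 2 / cfg$w0^2
  mu <- matrix(0, n_lines, n_px)
  block <- 8192L
  starts <- seq(1L, n_lines, by = block)
  for (i in seq_len(cfg$n_particles)) {
    sd_step <- sqrt(2 * pp$D[i] * lt)
    x <- pp$x0[i] + cumsum(rnorm(n_lines, 0, sd_step))
    y <- pp$y0[i] + cumsum(rnorm(n_lines, 0, sd_step))
    x <- if (is.na(pp$lo[i])) x else reflect_fold(x, pp$lo[i], pp$hi[i])
    ay <- pp$eps[i] * exp(-inv_w2 * wrap_min_image(y, cfg$box[2])^2)
    gate <- emission_gate(t_lines, cfg, t_total)
    if (!is.null(gate)) ay <- ay * gate
    periodic <- is.na(pp$lo[i])
    for (s in starts) {
      e <- min(s + block - 1L, n_lines)
      rows <- s:e
      dxm <- outer(x[rows], beam_x, `-`)
      if (periodic) dxm <- wrap_min_image(dxm, cfg$box[1])
      mu[rows, ] <- mu[rows, ] + ay[rows] * exp(-inv_w2 * dxm * dxm)
    }
  }
  mu
}

counts_from_intensity <- function(mu, cfg) {
  n <- length(mu)
  dims <- dim(mu)
  draw <- function(lambda) {
    m <- matrix(rpois(n, lambda), dims[1], dims[2])
    m
  }
  if (cfg$meta$n_channels == 2L) {
    ch1 <- draw(mu * cfg$channel_split + cfg$dark_rate)
    ch2 <- draw(mu * (1 - cfg$channel_split) + cfg$dark_rate)
    channels <- list(ch1, ch2)
  } else {
    channels <- list(draw(mu + cfg$dark_rate))
  }
  scan_data(channels, cfg$meta)
}
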