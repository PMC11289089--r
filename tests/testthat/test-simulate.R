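# Simulations here use the instrument optics and timing of the slow-raster
# and fast-linescan modes but shortened acquisitions, sized for test runtime;
# the methods vignette lists the depths used.

test_that("a fixed seed reproduces the scan bit-for-bit", {
  cfg <- sim_config(n_px = 256, n_lines = 8, n_particles = 20, seed = 9)
  a <- simulate_scan(cfg)
  b <- simulate_scan(cfg)
  expect_identical(a$channels, b$channels)
  cfg2 <- sim_config(n_px = 256, n_lines = 8, n_particles = 20, seed = 10)
  expect_false(identical(simulate_scan(cfg2)$channels, a$channels))
})

test_that("config validation guards box size, rates and regions", {
  expect_error(sim_config(box = c(1, 1)), class = "segfcs_validation_error")
  expect_error(sim_config(box = c(2, 2), n_px = 8192),
               class = "segfcs_validation_error")   # line longer than box
  expect_error(sim_config(dark_rate = -1), class = "segfcs_validation_error")
  expect_error(sim_config(triplet = list(f_tr = 1.2, tau_tr = 1e-5)),
               class = "segfcs_validation_error")
  base <- sim_config(n_px = 64, n_lines = 8)
  expect_error(make_two_region_config(base, split = 0, D_a = 1, D_b = 1),
               class = "segfcs_validation_error")
})

test_that("particle-free scans are pure uncorrelated background", {
  cfg <- sim_config(n_particles = 0, dark_rate = 0.1, n_px = 4096,
                    n_lines = 4, seed = 12)
  scan <- simulate_scan(cfg)
  expect_equal(mean(segfcs:::summed_counts(scan)), 2 * 0.1, tolerance = 0.05)
  sa <- scan_acfs(scan, "x", 4096, mode = "auto", max_lag = 64)
  bound <- 5 / sqrt(0.2^2 * 4096)   # counting-statistics scale for one line
  expect_true(all(abs(sa$G[-1, ]) < bound))
  # cross-correlation is flat even at lag 0
  sx <- scan_acfs(scan, "x", 4096, mode = "cross", max_lag = 64)
  cv <- average_acfs(sx)
  expect_lt(abs(cv$G[1]), bound)
})

test_that("frozen particles yield a time-invariant intensity pattern", {
  cfg <- sim_config(D = 0, n_particles = 15, scan_mode = "fast_x_linescan",
                    pixel_size = 194e-9, pixel_time = 3e-6,
                    line_frequency = 1800, n_px = 32, n_lines = 50,
                    box = c(6.5, 2), dark_rate = 0, seed = 4)
  mu <- withr::with_seed(cfg$seed, segfcs:::sim_intensity_fast(cfg))
  expect_equal(mu, matrix(mu[1, ], nrow(mu), ncol(mu), byrow = TRUE),
               tolerance = 1e-12)
})

test_that("mean counts follow the Gaussian-profile occupancy formula", {
  cfg <- sim_config(D = 20, n_particles = 300, n_px = 4096, n_lines = 24,
                    brightness = 0.5, dark_rate = 0.05, seed = 14)
  scan <- simulate_scan(cfg)
  dens <- cfg$n_particles / prod(cfg$box)
  expected <- dens * cfg$brightness * pi * cfg$w0^2 / 2 + 2 * cfg$dark_rate
  expect_equal(mean(segfcs:::summed_counts(scan)), expected, tolerance = 0.05)
})

test_that("correlation amplitude tracks the inverse focal particle number", {
  cfg <- sim_config(D = 100, n_particles = 200, n_lines = 48, seed = 15)
  scan <- simulate_scan(cfg)
  sa <- scan_acfs(scan, "x", 8192, mode = "cross", max_lag = 1024)
  cv <- average_acfs(sa)
  f <- fit_acf(cv, "diffusion_scan", w0 = 0.181,
               v = scan_speed(scan$meta) * 1e6, free = "offset")
  expect_equal(f$estimate[["G0"]], expected_G0(cfg), tolerance = 0.2)
  # and the averaged curve tracks the forward model within its own noise,
  # allowing for the finite-segment baseline of segment-normalized estimates
  tau_d <- cfg$w0^2 / (4 * cfg$D)
  T_seg <- 8192 * cfg$meta$pixel_time
  baseline <- 2 * expected_G0(cfg) * tau_d * log(1 + T_seg / tau_d) / T_seg
  idx <- 2:9
  model <- expected_G0(cfg) /
    (1 + 4 * cfg$D * cv$tau_s[idx] / cfg$w0^2) *
    exp(-(scan_speed(scan$meta) * 1e6 * cv$tau_s[idx] / cfg$w0)^2 /
          (1 + 4 * cfg$D * cv$tau_s[idx] / cfg$w0^2))
  expect_true(all(abs(cv$G[idx] - model) <= 3 * cv$sem[idx] + baseline))
})

test_that("triplet blinking is recovered by the triplet model fit", {
  cfg <- sim_config(D = 50, n_particles = 200, n_lines = 64, seed = 51,
                    triplet = list(f_tr = 0.25, tau_tr = 1e-5))
  scan <- simulate_scan(cfg)
  sa <- scan_acfs(scan, "x", 8192, mode = "cross", max_lag = 1024)
  cv <- average_acfs(sa)
  f <- fit_acf(cv, "diffusion_scan_triplet", w0 = 0.181,
               v = scan_speed(scan$meta) * 1e6, free = "offset")
  tau_tr_hat <- f$estimate[["tau_tr"]]
  f_tr_hat <- f$estimate[["A_tr"]] / (1 + f$estimate[["A_tr"]])
  expect_gt(tau_tr_hat, 1e-5 / 2)
  expect_lt(tau_tr_hat, 1e-5 * 2)
  expect_lt(abs(f_tr_hat - 0.25), 0.1)
})

test_that("two-region scans separate into classes matching the ground truth", {
  base <- sim_config(D = 10, n_particles = 700,
                     scan_mode = "fast_x_linescan", pixel_size = 194e-9,
                     pixel_time = 3e-6, line_frequency = 1800,
                     n_px = 64, n_lines = 8192, box = c(12.5, 2),
                     brightness = 0.5, seed = 31)
  cfg <- make_two_region_config(base, split = 0.5, D_a = 30, D_b = 10,
                                brightness_ratio = 3)
  expect_equal(nrow(cfg$regions), 2)
  scan <- simulate_scan(cfg)
  mp <- normalize_map(suppressMessages(segment_map(scan, "y", 1024)))
  sel <- select_segments(mp, thresholds = 0.5, labels = c("dim", "bright"))

  # ground truth: region of each pixel column's centre, skipping columns
  # within one spot radius of the boundary
  px_um <- 194e-9 * 1e6
  centers <- (sel$col - 0.5) * px_um
  boundary <- 0.5 * cfg$box[1]
  clear <- abs(centers - boundary) > cfg$w0
  truth <- ifelse(centers < boundary, "bright", "dim")
  agree <- as.character(sel$class[clear]) == truth[clear]
  expect_gt(mean(agree), 0.95)

  # map is bimodal: the two class means are well separated
  expect_gt(mean(mp$norm_mean[truth == "bright"]) /
              mean(mp$norm_mean[truth == "dim"]), 2)
})
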