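test_that("model family reduces correctly across its nested forms", {
  tau <- c(0, 10^seq(-6, -1, length.out = 40))
  # scanning term vanishes at v = 0
  expect_equal(acf_model(tau, 0.2, 50, 0.181, v = 0, model = "diffusion_scan"),
               acf_model(tau, 0.2, 50, 0.181, model = "diffusion"))
  # triplet term vanishes at A_tr = 0
  expect_equal(acf_model(tau, 0.2, 50, 0.181, v = 100, A_tr = 0,
                         model = "diffusion_scan_triplet"),
               acf_model(tau, 0.2, 50, 0.181, v = 100,
                         model = "diffusion_scan"))
  # half amplitude at the characteristic lag tau_D = w0^2 / (4 D)
  expect_equal(acf_model(0.181^2 / (4 * 106.4), 0.1, 106.4, 0.181,
                         model = "diffusion"), 0.05)
  # monotone non-increasing without a triplet term
  for (v in c(0, 15.4, 154)) {
    g <- acf_model(tau, 0.3, 20, 0.181, v = v, model = "diffusion_scan")
    expect_true(all(diff(g) <= 1e-15))
  }
  expect_error(acf_model(tau, -0.1, 50, 0.181),
               class = "segfcs_validation_error")
})

test_that("slow scanning is indistinguishable from a parked beam", {
  # at 1 Hz line rate (v = 15.4 um/s) the scanning factor stays ~1 over the
  # whole decay for cell-like D, so the plain diffusion model applies
  w0 <- 0.181
  for (D in c(10, 30, 100)) {
    tau_max <- 10 * w0^2 / (4 * D)
    tau <- seq(0, tau_max, length.out = 200)
    g_scan <- acf_model(tau, 0.2, D, w0, v = 15.4, model = "diffusion_scan")
    g_diff <- acf_model(tau, 0.2, D, w0, model = "diffusion")
    dev <- max(abs(g_scan - g_diff) / g_diff)
    # closed form: the deviation grows monotonically to its value at tau_max
    dev_exact <- 1 - exp(-(15.4 * tau_max / w0)^2 /
                           (1 + 4 * D * tau_max / w0^2))
    expect_equal(dev, dev_exact, tolerance = 1e-10)
    expect_lt(dev, 0.05)     # worst case (D = 10): ~3%
  }
})

test_that("Stokes-Einstein conversion reproduces solution-probe radii", {
  r_gfp <- stokes_einstein_radius(106.4) * 1e9
  expect_equal(round(r_gfp), 2)
  r_ab <- stokes_einstein_radius(48.6) * 1e9
  expect_lt(abs(r_ab - 4) / 4, 0.15)       # printed to one significant figure
  r_bead <- stokes_einstein_radius(6.6) * 1e9
  expect_lt(abs(r_bead - 32) / 32, 0.02)
  # inverse proportionality and round trip
  expect_equal(stokes_einstein_radius(2 * 106.4), stokes_einstein_radius(106.4) / 2)
  expect_equal(stokes_einstein_diffusion(stokes_einstein_radius(77)), 77)
  expect_error(stokes_einstein_radius(0), class = "segfcs_validation_error")
})

test_that("fits recover exact parameters from noiseless model curves", {
  tau <- (1:2048) * 3.05e-6
  g <- acf_model(tau, 0.1, 106.4, 0.181, v = 154, model = "diffusion_scan")
  cv <- segfcs:::new_fcs_acf(1:2048, g, tau_s = tau, mode = "auto")
  f <- fit_acf(cv, "diffusion_scan", w0 = 0.181, v = 154)
  expect_lt(abs(f$estimate[["G0"]] - 0.1) / 0.1, 1e-6)
  expect_lt(abs(f$estimate[["D"]] - 106.4) / 106.4, 1e-6)

  # calibration route: D fixed at reference, w0 free
  fc <- calibrate_w0(cv, D_ref = 106.4, v = 154, w0_init = 0.25)
  expect_lt(abs(fc$estimate[["w0"]] - 0.181) / 0.181, 1e-6)

  # triplet model self-consistency
  gt <- acf_model(tau, 0.1, 106.4, 0.181, v = 154, A_tr = 0.4,
                  tau_tr = 1e-5, model = "diffusion_scan_triplet")
  cvt <- segfcs:::new_fcs_acf(1:2048, gt, tau_s = tau, mode = "auto")
  ft <- fit_acf(cvt, "diffusion_scan_triplet", w0 = 0.181, v = 154)
  expect_lt(abs(ft$estimate[["A_tr"]] - 0.4) / 0.4, 1e-4)
  expect_lt(abs(ft$estimate[["tau_tr"]] - 1e-5) / 1e-5, 1e-4)
})

test_that("D recovery from noisy curves is essentially unbiased", {
  set.seed(77)
  tau <- (1:512) * 3.05e-6
  g0 <- 0.2
  truth <- acf_model(tau, g0, 100, 0.181, v = 154, model = "diffusion_scan")
  ds <- replicate(100, {
    cv <- segfcs:::new_fcs_acf(1:512, truth + rnorm(512, 0, 0.05 * g0),
                               tau_s = tau, mode = "auto")
    fit_acf(cv, "diffusion_scan", w0 = 0.181, v = 154)$estimate[["D"]]
  })
  expect_lt(abs(mean(ds) - 100) / 100, 0.05)
})

test_that("degenerate inputs produce explicit fit errors", {
  tau <- (1:64) * 1e-5
  flat <- segfcs:::new_fcs_acf(1:64, rep(0, 64), tau_s = tau, mode = "auto")
  expect_error(fit_acf(flat, "diffusion", w0 = 0.181),
               class = "segfcs_fit_error")
  expect_error(calibrate_w0(flat, D_ref = 395), class = "segfcs_fit_error")
  expect_error(calibrate_w0(flat, D_ref = -1),
               class = "segfcs_validation_error")
  ok <- segfcs:::new_fcs_acf(1:64, acf_model(tau, 0.1, 50, 0.181),
                             tau_s = tau, mode = "auto")
  expect_error(fit_acf(ok, "diffusion", w0 = 0.181, fit_range = c(1, 2)),
               class = "segfcs_validation_error")
})

test_that("tidy and glance expose estimates, errors and fit quality", {
  tau <- (1:256) * 1e-5
  g <- acf_model(tau, 0.15, 30, 0.181)
  set.seed(3)
  cv <- segfcs:::new_fcs_acf(1:256, g + rnorm(256, 0, 0.002), tau_s = tau,
                             mode = "cross")
  f <- fit_acf(cv, "diffusion", w0 = 0.181)
  td <- tidy(f)
  expect_setequal(td$term, c("G0", "D", "w0", "v", "A_tr", "tau_tr", "offset"))
  expect_true(all(is.finite(td$std.error[!td$fixed])))
  expect_true(all(is.na(td$std.error[td$fixed])))
  gl <- glance(f)
  expect_true(gl$converged)
  expect_gt(gl$reduced_chisq, 0)
  expect_s3_class(autoplot(f), "ggplot")
})
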