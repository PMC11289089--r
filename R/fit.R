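#' Fit a diffusion model to an averaged correlation curve
#'
#' Nonlinear least-squares fit (Levenberg--Marquardt with box constraints)
#' of one of the [acf_model()] models to a correlation curve. Following
#' standard FCS practice, the observation-spot radius `w0` (from
#' calibration) and the scan speed `v` (from the acquisition settings) are
#' fixed, and only `G0`, `D` (and the triplet terms, when that model is
#' chosen) are free. Any parameter can be fixed to a value through `fixed`
#' or freed by name through `free` — this is how [calibrate_w0()] fits `w0`
#' with a reference `D`.
#'
#' The zero lag is excluded for autocorrelations (it carries the shot-noise
#' spike) and included for cross-correlations (two-channel splitting removes
#' detector noise); override with `include_lag0`.
#'
#' Default initialization: `G0` from the mean of the first three fitted
#' lags; `D` from the half-decay lag via `tau_half = w0^2 / (4 D)`;
#' `A_tr = 0.5` and `tau_tr = 5e-6` s when the triplet term is enabled.
#'
#' Besides the model parameters, a constant baseline term `offset` is
#' available (fixed at 0 by default; free it with `free = "offset"`).
#' Segment-normalized correlation estimates sit on a small negative baseline
#' of order `-(2 / T) * integral(G)` — each segment is normalized by its own
#' finite-duration mean — and freeing the baseline absorbs that bias instead
#' of letting it masquerade as faster diffusion.
#'
#' @param curve An `fcs_acf` tibble with `tau_s` filled in.
#' @param model One of `"diffusion"`, `"diffusion_scan"`,
#'   `"diffusion_scan_triplet"`.
#' @param w0 Observation-spot 1/e^2 radius in um (fixed unless freed).
#' @param v Scan speed in um/s (fixed; required by the scan models).
#' @param fixed Named list of additional parameters to fix (e.g.
#'   `list(D = 395)`).
#' @param free Character vector of parameter names to free (e.g. `"w0"`).
#' @param init Named list overriding the default starting values.
#' @param fit_range Length-2 numeric, the tau range (seconds) to fit;
#'   default: all computed lags.
#' @param weights `"none"` (default, unweighted) or `"sem"` (weights
#'   `1/sem^2`, usable when the curve averages several segments).
#' @param include_lag0 Logical; default by curve mode as described above.
#' @return An object of class `fcs_fit`; see [tidy.fcs_fit()],
#'   [glance.fcs_fit()], `predict()`, [autoplot.fcs_fit].
#' @export
fit_acf <- function(curve, model = c("diffusion", "diffusion_scan",
                                     "diffusion_scan_triplet"),
                    w0, v = 0, fixed = NULL, free = NULL, init = NULL,
                    fit_range = NULL, weights = c("none", "sem"),
                    include_lag0 = NULL) {
  model <- match.arg(model)
  weights <- match.arg(weights)
  if (missing(w0) || is.null(w0)) stop_validation("`w0` must be supplied (um).")
  if (any(!is.finite(curve$tau_s))) {
    stop_validation("curve has no temporal axis; call to_temporal() first.")
  }
  par_names <- c("G0", "D", "w0", "v", "A_tr", "tau_tr", "offset")
  full <- c(G0 = NA_real_, D = NA_real_, w0 = w0, v = v, A_tr = 0,
            tau_tr = 5e-6, offset = 0)
  free_names <- c("G0", "D")
  if (model == "diffusion_scan_triplet") {
    free_names <- c(free_names, "A_tr", "tau_tr")
  }
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), par_names)
    if (length(bad)) stop_validation(paste0("unknown parameter(s): ",
                                            paste(bad, collapse = ", ")))
    full[names(fixed)] <- unlist(fixed)
    free_names <- setdiff(free_names, names(fixed))
  }
  if (!is.null(free)) {
    bad <- setdiff(free, par_names)
    if (length(bad)) stop_validation(paste0("unknown parameter(s): ",
                                            paste(bad, collapse = ", ")))
    free_names <- union(free_names, free)
  }
  if (length(free_names) == 0) stop_validation("no free parameters to fit.")

  mode <- attr(curve, "mode") %||% "auto"
  if (is.null(include_lag0)) include_lag0 <- identical(mode, "cross")
  keep <- rep(TRUE, nrow(curve))
  if (!include_lag0) keep <- keep & curve$lag_px > 0L
  if (!is.null(fit_range)) {
    keep <- keep & curve$tau_s >= fit_range[1] & curve$tau_s <= fit_range[2]
  }
  tau <- curve$tau_s[keep]
  g <- curve$G[keep]
  if (length(tau) < 2 * length(free_names)) {
    stop_validation(sprintf(
      "fit range leaves %d usable lag(s) for %d free parameter(s).",
      length(tau), length(free_names)))
  }
  wts <- rep(1, length(tau))
  if (weights == "sem") {
    s <- curve$sem[keep]
    if (all(s > 0)) wts <- 1 / s^2 else
      warn("sem contains zeros; falling back to unweighted fit.")
  }

  # starting values
  g0_init <- mean(head(g, 3))
  if (!is.finite(g0_init) || g0_init <= 0) {
    stop_fit("no positive correlation amplitude: nothing to fit.")
  }
  w0_init <- full[["w0"]]
  half_idx <- which(g <= g0_init / 2)
  tau_half <- if (length(half_idx)) tau[min(half_idx)] else max(tau)
  if (tau_half <= 0) tau_half <- max(tau[tau > 0])
  d_init <- w0_init^2 / (4 * tau_half)
  start_full <- full
  start_full[["G0"]] <- g0_init
  start_full[["D"]] <- if (is.na(full[["D"]])) d_init else full[["D"]]
  start_full[["A_tr"]] <- if ("A_tr" %in% free_names) 0.5 else full[["A_tr"]]
  if (!is.null(init)) start_full[names(init)] <- unlist(init)
  if (is.na(start_full[["D"]])) start_full[["D"]] <- d_init

  lower_full <- c(G0 = 0, D = 0, w0 = 1e-4, v = 0, A_tr = 0, tau_tr = 1e-9,
                  offset = -Inf)
  start <- start_full[free_names]
  lower <- lower_full[free_names]

  fn <- function(p) {
    pars <- start_full
    pars[free_names] <- p
    sqrt(wts) * (g - pars[["offset"]] -
                   acf_model(tau, pars[["G0"]], pars[["D"]], pars[["w0"]],
                             pars[["v"]], pars[["A_tr"]], pars[["tau_tr"]],
                             model = model))
  }
  res <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, fn = fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop_fit(paste0("fit failed: ", conditionMessage(e))))
  if (!(res$info %in% 1:3)) {
    stop_fit(sprintf("fit did not converge (Levenberg-Marquardt info %d: %s).",
                     res$info, res$message))
  }
  est_full <- start_full
  est_full[free_names] <- res$par

  n <- length(tau); p <- length(free_names)
  rss <- sum(res$fvec^2)
  red_chisq <- rss / (n - p)
  se <- setNames(rep(NA_real_, p), free_names)
  # nls.lm's hessian is the Gauss-Newton J'J; cov(theta) = s^2 (J'J)^-1
  cov <- tryCatch(red_chisq * solve(res$hessian),
                  error = function(e) NULL)
  if (!is.null(cov)) {
    d <- diag(cov)
    se[d >= 0] <- sqrt(d[d >= 0])
  }

  fitted <- est_full[["offset"]] +
    acf_model(tau, est_full[["G0"]], est_full[["D"]],
              est_full[["w0"]], est_full[["v"]], est_full[["A_tr"]],
              est_full[["tau_tr"]], model = model)
  structure(
    list(model = model,
         estimate = est_full,
         free = free_names,
         std_error = se,
         fixed = as.list(est_full[setdiff(par_names, free_names)]),
         reduced_chisq = red_chisq,
         fit_range = range(tau),
         n_lags = n,
         n_segments = curve$n_segments[1] %||% 1L,
         converged = TRUE,
         data = tibble(tau_s = tau, G = g, weight = wts, fitted = fitted)),
    class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<fcs_fit> model %s, %d lags, %d segment(s)\n",
              x$model, x$n_lags, x$n_segments))
  co <- tidy(x)
  co$estimate <- signif(co$estimate, digits)
  co$std.error <- signif(co$std.error, digits)
  print.data.frame(as.data.frame(co), row.names = FALSE)
  cat(sprintf("  reduced chi-square: %.4g\n", x$reduced_chisq))
  invisible(x)
}

#' @export
coef.fcs_fit <- function(object, ...) object$estimate

#' Tidy a correlation-curve fit
#'
#' @param x An `fcs_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per model parameter: `term`, `estimate`,
#'   `std.error` (NA for fixed parameters), `fixed`. `D` is in um^2/s, `w0`
#'   in um, `v` in um/s, `tau_tr` in seconds.
#' @export
tidy.fcs_fit <- function(x, ...) {
  terms <- names(x$estimate)
  tibble(term = terms,
         estimate = unname(x$estimate),
         std.error = unname(x$std_error[terms]),
         fixed = !(terms %in% x$free))
}

#' @rdname tidy.fcs_fit
#' @return [glance.fcs_fit()] returns a one-row tibble with the model id,
#'   reduced chi-square, lag count, segment count and convergence flag.
#' @export
glance.fcs_fit <- function(x, ...) {
  tibble(model = x$model, reduced_chisq = x$reduced_chisq,
         n_lags = x$n_lags, n_segments = x$n_segments,
         converged = x$converged)
}

#' @export
predict.fcs_fit <- function(object, tau = NULL, ...) {
  tau <- tau %||% object$data$tau_s
  e <- object$estimate
  e[["offset"]] +
    acf_model(tau, e[["G0"]], e[["D"]], e[["w0"]], e[["v"]], e[["A_tr"]],
              e[["tau_tr"]], model = object$model)
}

#' Calibrate the observation-spot radius with a reference fluorophore
#'
#' Fits a correlation curve measured on a dye of known diffusion coefficient
#' with `D` fixed to the reference value and `w0` free, returning the
#' calibrated lateral 1/e^2 radius of the observation spot. This is the
#' standard first step before sample fits, where `w0` is then held fixed.
#'
#' @param curve An `fcs_acf` tibble from the reference measurement.
#' @param D_ref Reference diffusion coefficient in um^2/s (> 0).
#' @param model Fit model (default `"diffusion_scan"`, matching a slow-scan
#'   calibration acquisition).
#' @param v Scan speed in um/s.
#' @param w0_init Starting value for `w0`, um.
#' @param free Additional parameters to free alongside `w0` (e.g.
#'   `"offset"` for a baseline term).
#' @param ... Passed on to [fit_acf()].
#' @return An `fcs_fit`; the calibrated radius is
#'   `coef(fit)[["w0"]]` with uncertainty `fit$std_error[["w0"]]`.
#' @export
calibrate_w0 <- function(curve, D_ref, model = "diffusion_scan", v = 0,
                         w0_init = 0.2, free = NULL, ...) {
  if (!is.numeric(D_ref) || length(D_ref) != 1 || D_ref <= 0) {
    stop_validation("`D_ref` must be a single positive number (um^2/s).")
  }
  fit_acf(curve, model = model, w0 = w0_init, v = v,
          fixed = list(D = D_ref), free = union("w0", free), ...)
}
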