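#' Diffusion models for scanned FCS curves
#'
#' Evaluates the temporal correlation model `G(tau) = G_diff(tau) * S(tau) *
#' T(tau)` used to fit averaged curves:
#'
#' * `"diffusion"` — free 2D Gaussian diffusion only,
#'   `G(tau) = G0 / (1 + 4 D tau / w0^2)`; appropriate for Y-segmented fast
#'   line scans, where the speed along the segmentation axis is zero.
#' * `"diffusion_scan"` — multiplies the diffusion term by the scanning
#'   component `S(tau) = exp(-(v tau / w0)^2 / (1 + 4 D tau / w0^2))`,
#'   accounting for the focus moving at speed `v` during a slow scan.
#' * `"diffusion_scan_triplet"` — multiplies further by the triplet term
#'   `T(tau) = 1 + A_tr * exp(-tau / tau_tr)`, with
#'   `A_tr = f_tr / (1 - f_tr)` for a dark-state fraction `f_tr` and triplet
#'   correlation time `tau_tr`.
#'
#' Units are standardized throughout: `tau` in seconds, `D` in um^2/s, `w0`
#' (the 1/e^2 lateral radius of the observation spot) in um, `v` in um/s,
#' `tau_tr` in seconds.
#'
#' @param tau Lag times in seconds (>= 0).
#' @param G0 Amplitude (dimensionless). Inversely proportional to the number
#'   of particles in the observation area.
#' @param D Diffusion coefficient, um^2/s.
#' @param w0 1/e^2 lateral radius of the observation spot, um.
#' @param v Scan speed, um/s (ignored by `"diffusion"`).
#' @param A_tr Triplet amplitude `f_tr / (1 - f_tr)` (>= 0).
#' @param tau_tr Triplet time constant, seconds.
#' @param model Model identifier (see above).
#' @return Numeric vector of model correlation amplitudes.
#' @examples
#' tau <- c(0, 77e-6) # second value: w0^2/(4 D) for D = 106.4, w0 = 0.181
#' acf_model(tau, G0 = 0.1, D = 106.4, w0 = 0.181) # 0.1, 0.05
#' @export
acf_model <- function(tau, G0, D, w0, v = 0, A_tr = 0, tau_tr = 5e-6,
                      model = c("diffusion", "diffusion_scan",
                                "diffusion_scan_triplet")) {
  model <- match.arg(model)
  pars <- c(G0 = G0, D = D, w0 = w0, v = v, A_tr = A_tr, tau_tr = tau_tr)
  if (any(!is.finite(pars))) stop_validation("model parameters must be finite.")
  if (G0 < 0 || D < 0 || w0 <= 0 || v < 0 || A_tr < 0 || tau_tr <= 0) {
    stop_validation("parameters out of range: need G0, D, A_tr >= 0 and w0, tau_tr, v >= 0 (w0, tau_tr > 0).")
  }
  denom <- 1 + 4 * D * tau / w0^2
  g <- G0 / denom
  if (model %in% c("diffusion_scan", "diffusion_scan_triplet")) {
    g <- g * exp(-(v * tau / w0)^2 / denom)
  }
  if (model == "diffusion_scan_triplet") {
    g <- g * (1 + A_tr * exp(-tau / tau_tr))
  }
  g
}

#' Hydrodynamic radius from a diffusion coefficient
#'
#' Applies the Stokes--Einstein relation `D = k_B T / (6 pi eta R_H)` to
#' convert a measured diffusion coefficient into the hydrodynamic radius of
#' the diffusing species. Defaults describe aqueous solution at 20 C.
#'
#' @param D Diffusion coefficient in um^2/s (> 0).
#' @param temperature Absolute temperature in kelvin (default 293.15 K).
#' @param viscosity Dynamic viscosity in Pa s (default 0.001, water).
#' @return Hydrodynamic radius in metres.
#' @examples
#' stokes_einstein_radius(106.4) * 1e9 # ~2 nm (GFP-sized)
#' stokes_einstein_radius(6.6) * 1e9   # ~32 nm
#' @export
stokes_einstein_radius <- function(D, temperature = 293.15,
                                   viscosity = 0.001) {
  if (any(D <= 0)) stop_validation("`D` must be > 0.")
  if (temperature <= 0 || viscosity <= 0) {
    stop_validation("temperature and viscosity must be > 0.")
  }
  k_b <- 1.380649e-23
  k_b * temperature / (6 * pi * viscosity * (D * 1e-12))
}

#' @rdname stokes_einstein_radius
#' @param radius Hydrodynamic radius in metres (> 0).
#' @return [stokes_einstein_diffusion()] returns `D` in um^2/s.
#' @export
stokes_einstein_diffusion <- function(radius, temperature = 293.15,
                                      viscosity = 0.001) {
  if (any(radius <= 0)) stop_validation("`radius` must be > 0.")
  k_b <- 1.380649e-23
  k_b * temperature / (6 * pi * viscosity * radius) * 1e12
}
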