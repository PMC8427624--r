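#' Physical constants for the hydraulic variables
#'
#' Defaults are the study constants: g = 9.8 m/s^2, kinematic viscosity
#' nu = 1.76e-5 m^2/s, dynamic viscosity mu = 1.73e-4 Pa s, water density
#' rho = 996 kg/m^3 (average 28 C), substrate density rho_s = 273 kg/m^3,
#' Shields parameter theta_c = 0.035, and the velocity-gradient reference
#' depth y_ref = 0.01 m (velocity measured 1 cm above the bed, no-slip at the
#' bed).
#'
#' Note that the default substrate density (273 kg/m^3) is *below* the water
#' density, which makes the critical shear stress negative. It is kept as the
#' documented default for fidelity with the source constants; quartz-sand
#' substrate corresponds to `rho_s = 2730`, available as an override (see
#' [substrate_flow_metrics()], which warns whenever `rho_s < rho`).
#'
#' @param g,nu,mu,rho,rho_s,theta_c,y_ref overrides, all strictly positive.
#' @return a list of class `hydraulic_constants`.
#' @export
hydraulic_constants <- function(g = 9.8, nu = 1.76e-5, mu = 1.73e-4,
                                rho = 996, rho_s = 273, theta_c = 0.035,
                                y_ref = 0.01) {
  consts <- list(g = g, nu = nu, mu = mu, rho = rho, rho_s = rho_s,
                 theta_c = theta_c, y_ref = y_ref)
  if (any(vapply(consts, function(v) !is.finite(v) || v <= 0, logical(1))))
    stop_invalid("all hydraulic constants must be finite and positive")
  structure(consts, class = "hydraulic_constants")
}

#' Near-bed hydraulic variables from a flow observation
#'
#' Computes the flow-dependent hydraulic variables from near-bed current
#' velocity `U` (m/s, measured 1 cm above the bed) and depth `d` (m):
#'
#' * Froude number `Fr = U^2 / (g d)` (as printed in the source variable
#'   table; the conventional `U / sqrt(g d)` is available via
#'   `froude = "conventional"`),
#' * Reynolds number `Re = U d / nu`,
#' * shear stress `tau = mu * (dv/dy)` with the two-point velocity gradient
#'   `dv/dy = U / y_ref`,
#' * shear velocity `V = sqrt(tau / rho)`,
#' * stream power `w_a = tau * U`.
#'
#' All inputs and outputs are SI; millimetres appear only in the grain-size
#' interface.
#'
#' @param U near-bed current velocity, m/s, nonnegative. Vectorized.
#' @param d water depth, m, strictly positive. Vectorized.
#' @param consts a [hydraulic_constants()] object.
#' @param froude `"printed"` (default) or `"conventional"`.
#' @return data frame with columns `Fr`, `Re`, `tau`, `V`, `w_a`.
#' @export
#' @examples
#' flow_metrics(0.4, 1.0)
flow_metrics <- function(U, d, consts = hydraulic_constants(),
                         froude = c("printed", "conventional")) {
  froude <- match.arg(froude)
  if (any(!is.finite(U)) || any(U < 0)) stop_invalid("U must be >= 0")
  if (any(!is.finite(d)) || any(d <= 0)) stop_invalid("depth d must be > 0")
  Fr <- if (froude == "printed") U^2 / (consts$g * d) else U / sqrt(consts$g * d)
  dvdy <- U / consts$y_ref
  tau <- consts$mu * dvdy
  V <- sqrt(tau / consts$rho)
  data.frame(Fr = Fr, Re = U * d / consts$nu, tau = tau, V = V, w_a = tau * U)
}

#' Substrate-dependent hydraulic variables
#'
#' Boundary Reynolds number `Re* = V ks / nu` and critical shear stress
#' `tau_c = theta_c g D50 (rho_s - rho)`. `ks` and `D50` are supplied in mm
#' (the grain-size interface unit) and converted to metres internally.
#'
#' Under the default substrate density (273 kg/m^3 < water density) `tau_c`
#' is negative; a warning is emitted whenever `rho_s < rho`.
#'
#' @param V shear velocity, m/s, nonnegative. Vectorized.
#' @param D50 median grain diameter, mm.
#' @param ks bed roughness, mm (normally `2 * D50`).
#' @param consts a [hydraulic_constants()] object.
#' @return data frame with columns `Re_star`, `tau_c`.
#' @export
substrate_flow_metrics <- function(V, D50, ks, consts = hydraulic_constants()) {
  if (any(!is.finite(V)) || any(V < 0)) stop_invalid("V must be >= 0")
  if (any(!is.finite(D50)) || any(D50 <= 0) || any(!is.finite(ks)) || any(ks <= 0))
    stop_invalid("D50 and ks must be positive (mm)")
  if (consts$rho_s < consts$rho)
    warning("substrate density rho_s (", consts$rho_s,
            " kg/m^3) is below water density; critical shear stress is negative",
            call. = FALSE)
  data.frame(Re_star = V * (ks / 1000) / consts$nu,
             tau_c = consts$theta_c * consts$g * (D50 / 1000) *
               (consts$rho_s - consts$rho))
}

#' Per-plot hydraulic table
#'
#' Joins the grain metrics and the hydraulic variables for every plot in a
#' survey table, for one flow period. Expects columns `U_<period>` and
#' `d_<period>` (m/s, m) plus either precomputed grain columns (`D50`,
#' `D_mean`, `So`, `ks`) or wide sieve columns for [grain_table()].
#'
#' Plots missing the requested flow observation are kept and flagged (their
#' flow-dependent columns are `NA` and `flow_missing` is `TRUE`); the count of
#' flagged rows is reported with a message, never silently dropped.
#'
#' @param plots plot table (one row per 1-m^2 plot).
#' @param consts a [hydraulic_constants()] object.
#' @param period `"low"` or `"high"`.
#' @param froude passed to [flow_metrics()].
#' @return `plots` with columns `Fr`, `Re`, `Re_star`, `V`, `tau`, `tau_c`,
#'   `w_a`, the grain columns, and `flow_missing`.
#' @export
hydraulic_table <- function(plots, consts = hydraulic_constants(),
                            period = c("low", "high"),
                            froude = c("printed", "conventional")) {
  period <- match.arg(period)
  froude <- match.arg(froude)
  if (nrow(plots) == 0) {
    out <- cbind(plots,
                 data.frame(Fr = numeric(0), Re = numeric(0), tau = numeric(0),
                            V = numeric(0), w_a = numeric(0),
                            Re_star = numeric(0), tau_c = numeric(0),
                            flow_missing = logical(0)))
    return(out)
  }
  if (!all(c("D50", "D_mean", "So", "ks") %in% names(plots)))
    plots <- grain_table(plots)
  ucol <- paste0("U_", period); dcol <- paste0("d_", period)
  if (!all(c(ucol, dcol) %in% names(plots)))
    stop_invalid("plot table lacks columns ", ucol, ", ", dcol)
  U <- plots[[ucol]]; d <- plots[[dcol]]
  miss <- !is.finite(U) | !is.finite(d)
  if (any(miss))
    message(sum(miss), " plot(s) lack a ", period,
            "-flow observation; rows flagged, not dropped")
  fm <- data.frame(Fr = rep(NA_real_, nrow(plots)), Re = NA_real_,
                   tau = NA_real_, V = NA_real_, w_a = NA_real_)
  if (any(!miss))
    fm[!miss, ] <- flow_metrics(U[!miss], d[!miss], consts, froude)
  sm <- data.frame(Re_star = rep(NA_real_, nrow(plots)), tau_c = NA_real_)
  if (any(!miss))
    sm[!miss, ] <- suppressWarnings(
      substrate_flow_metrics(fm$V[!miss], plots$D50[!miss], plots$ks[!miss],
                             consts))
  if (consts$rho_s < consts$rho)
    warning("substrate density rho_s < water density; tau_c is negative",
            call. = FALSE)
  cbind(plots, fm, sm, flow_missing = miss)
}
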