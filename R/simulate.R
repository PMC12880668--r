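#' Physiological parameters for one 24h simulation
#'
#' Flat bundle of the constants needed to simulate a single window. Event
#' level modifiers (meal offsets, bolus coefficients, ...) travel on the
#' event tables of the [sample24h()] instead. Defaults are the prior
#' centers used by [vp_priors()].
#'
#' @param VG glucose distribution volume (dL).
#' @param GEZI glucose effectiveness at zero insulin (1/min).
#' @param EGP endogenous glucose production (mg/dL/min).
#' @param SIE mean insulin sensitivity (per U/min of chain output).
#' @param SIA intraday sinusoid amplitude, in `[0, 0.5]`.
#' @param SIphi intraday sinusoid phase (fraction of a day).
#' @param tauG subcutaneous lag (min).
#' @param tauI1,tauI2,tauI3,tauI4 insulin-chain time constants (min);
#'   `tauI1` is the patient-level value used for basal insulin and as the
#'   default bolus first stage.
#' @param tauD1 first meal-absorption time constant (min).
#' @param tauE metabolic time constant (min).
#' @param SE metabolic-rate gain (mg/dL/min per unit E).
#' @param H hypoglycemia amplification coefficient (>= 0).
#' @param Gth hypoglycemia threshold (mg/dL).
#' @param sigma CGM noise standard deviation (mg/dL).
#' @param X0,S0,Ip0 initial insulin-chain state.
#' @return object of class `sim_params` (named list).
#' @export
sim_params <- function(VG = 120, GEZI = 2.5e-3, EGP = 1.2, SIE = 0.3,
                       SIA = 0.2, SIphi = 0, tauG = 15, tauI1 = 16,
                       tauI2 = 60, tauI3 = 60, tauI4 = 30, tauD1 = 5,
                       tauE = 10, SE = 0.01, H = 0.3, Gth = 70, sigma = 12,
                       X0 = 0.008, S0 = 0.015, Ip0 = 0.015) {
  p <- list(VG = VG, GEZI = GEZI, EGP = EGP, SIE = SIE, SIA = SIA,
            SIphi = SIphi, tauG = tauG, tauI1 = tauI1, tauI2 = tauI2,
            tauI3 = tauI3, tauI4 = tauI4, tauD1 = tauD1, tauE = tauE,
            SE = SE, H = H, Gth = Gth, sigma = sigma, X0 = X0, S0 = S0,
            Ip0 = Ip0)
  taus <- c(tauG, tauI1, tauI2, tauI3, tauI4, tauD1, tauE)
  if (any(taus <= 0)) stop("all time constants must be positive")
  if (VG <= 0) stop("VG must be positive")
  if (SIA < 0 || SIA > 0.5) stop("SIA must lie in [0, 0.5]")
  if (H < 0) stop("H must be non-negative")
  if (sigma <= 0) stop("sigma must be positive")
  structure(p, class = "sim_params")
}

# header slot order shared with the C++ engine
.slot_header <- c("VG", "GEZI", "EGP", "SIE", "SIA", "SIphi", "tauG",
                  "tauI1", "tauI2", "tauI3", "tauI4", "tauE", "SE", "H",
                  "Gth", "sigma", "X0", "S0", "Ip0", "tauD1")

# slot vector = header + per-event parameters, defaults where a modifier
# column is absent from the event table
params_to_slots <- function(params, s) {
  z <- unlist(params[.slot_header], use.names = FALSE)
  gete <- function(d, col, def) if (col %in% names(d)) d[[col]] else rep(def, nrow(d))
  zm <- zb <- ze <- numeric(0)
  if (nrow(s$meals) > 0)
    zm <- as.numeric(t(cbind(gete(s$meals, "TD", 0),
                             gete(s$meals, "tauD2", 48),
                             gete(s$meals, "MA", 1))))
  if (nrow(s$boluses) > 0)
    zb <- as.numeric(t(cbind(gete(s$boluses, "TI", 0),
                             gete(s$boluses, "tauI1", params$tauI1),
                             gete(s$boluses, "IA", 1))))
  if (nrow(s$exercise) > 0)
    ze <- as.numeric(t(cbind(gete(s$exercise, "TP", 0),
                             gete(s$exercise, "tauP_long", 1040),
                             gete(s$exercise, "tauP_short", 45),
                             gete(s$exercise, "P_long", 0.4),
                             gete(s$exercise, "P_short", 0))))
  c(z, zm, zb, ze)
}

#' Simulate one 24h window
#'
#' Runs the deterministic submodel for a window. With the default
#' `analytic_forcing` backend the linear chains (meal, insulin, physical
#' activity, metabolic rate) are evaluated through their closed-form
#' impulse responses and only the nonlinear glucose / sensor pair (plus the
#' sensitivity-driven final insulin stage) is integrated with a fixed-step
#' RK4, with sub-steps at event onsets. The `full_ode` backend integrates
#' every compartment numerically at step `ode_dt` and serves as a
#' brute-force cross-check.
#'
#' @param params a [sim_params()].
#' @param sample a [sample24h()]; event tables may carry per-event modifier
#'   columns (`TD`, `tauD2`, `MA`; `TI`, `tauI1`, `IA`; `TP`, `tauP_long`,
#'   `tauP_short`, `P_long`, `P_short`).
#' @param dt output grid step (min); the grid spans `[0, 1440]`.
#' @param backend `"analytic_forcing"` or `"full_ode"`.
#' @param ode_dt integration step of the `full_ode` backend (min).
#' @return a `trace_bundle`: data.frame-like list with `t`, `SG`, `G`, `X`,
#'   `RA`, `PA`, `SI`, `E`, `FR` on the grid.
#' @export
simulate_sample <- function(params, sample, dt = 1,
                            backend = c("analytic_forcing", "full_ode"),
                            ode_dt = 0.25) {
  backend <- match.arg(backend)
  stopifnot(inherits(params, "sim_params"), inherits(sample, "sample24h"))
  z <- params_to_slots(params, sample)
  ed <- as_engine_data(sample)
  out <- cpp_simulate(z, ed, dt, backend, ode_dt)
  if (!out$ok)
    stop(sprintf("glucose left the integrable range at t = %.1f min",
                 out$bad_time), call. = FALSE)
  out$ok <- NULL; out$bad_time <- NULL
  structure(out, class = "trace_bundle")
}

#' @export
print.trace_bundle <- function(x, ...) {
  n <- length(x$t)
  cat(sprintf("<trace_bundle> %d points over %.0f min\n", n, x$t[n]))
  cat(sprintf("  SG %.0f-%.0f mg/dL, G %.0f-%.0f mg/dL, max RA %.2f, max X %.4f\n",
              min(x$SG), max(x$SG), min(x$G), max(x$G), max(x$RA), max(x$X)))
  invisible(x)
}

#' @export
as.data.frame.trace_bundle <- function(x, ...) {
  as.data.frame(unclass(x), ...)
}

#' Write a trace bundle to CSV
#'
#' One row per grid point, columns `t_min` plus each simulated signal.
#'
#' @param trace a `trace_bundle`.
#' @param file output path.
#' @export
write_trace <- function(trace, file) {
  d <- as.data.frame(trace)
  names(d)[1] <- "t_min"
  write.csv(d, file, row.names = FALSE)
  invisible(file)
}
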