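#' Rate of glucose appearance from a meal
#'
#' Third-order meal-absorption chain: an impulse of carbohydrate mass enters
#' a cascade of three unit-DC-gain first-order stages with time constants
#' `tauD1, tauD2, tauD2` (the repeated stage is handled in confluent form).
#' The injected mass is `0.8 * MA * carbs * 1000 / VG` mg/dL, i.e. a fixed
#' carbohydrate bioavailability of 0.8 scaled by the meal coefficient and the
#' glucose distribution volume, so that `VG * integral(RA) = 0.8 * MA *
#' carbs * 1000` mg.
#'
#' @param t_grid evaluation times (min), uniform or not.
#' @param carbs carbohydrate content (g), >= 0.
#' @param VG glucose distribution volume (dL).
#' @param tauD1,tauD2 absorption time constants (min), > 0.
#' @param MA meal coefficient (dimensionless, > 0); uncertainty in the
#'   self-reported carbohydrate content.
#' @param t_report reported meal time (min from window start).
#' @param TD start offset added to the reported time (min, may be negative).
#' @return numeric vector, rate of appearance (mg/dL/min) on `t_grid`.
#' @export
#' @examples
#' t <- 0:600
#' ra <- meal_ra(t, carbs = 60, VG = 100, tauD1 = 10, tauD2 = 40)
#' sum(ra) # ~ 0.8 * 60 * 1000 / 100 = 480
meal_ra <- function(t_grid, carbs, VG, tauD1, tauD2, MA = 1,
                    t_report = 0, TD = 0) {
  if (tauD1 <= 0 || tauD2 <= 0) stop("meal time constants must be positive")
  if (carbs < 0) stop("carbs must be non-negative")
  if (VG <= 0) stop("VG must be positive")
  if (carbs == 0) return(numeric(length(t_grid)))
  mass <- 0.8 * MA * carbs * 1000 / VG
  cpp_chain_impulse(as.numeric(t_grid), t_report + TD, mass,
                    c(tauD1, tauD2, tauD2))
}

#' Plasma-insulin signal from boluses, basal and initial state
#'
#' Three cascaded unit-DC-gain first-order stages (`tauI1` per injection,
#' then shared `tauI2`, `tauI3`). Boluses enter as impulses of mass
#' `IA * dose` at `t_report + TI`; long-acting basal enters as a constant
#' rate (U/min) into the first compartment for the whole window; the
#' window-start compartment contents `S0` (first two stages) and `Ip0` decay
#' through the remaining stages.
#'
#' @param t_grid evaluation times (min).
#' @param boluses data.frame with columns `t_report`, `dose` (U), and
#'   optionally `TI` (min), `tauI1` (min), `IA`; missing columns default to
#'   `0`, `tauI1p`, `1`.
#' @param basal_rate constant basal infusion (U/min).
#' @param tauI1p patient-level first-stage time constant (min), used for the
#'   basal pathway and as default for boluses.
#' @param tauI2,tauI3 shared chain time constants (min); may be equal.
#' @param S0 initial content of the first two compartments (U/min units).
#' @param Ip0 initial plasma-insulin compartment value.
#' @return numeric vector `Ip(t)` on `t_grid`.
#' @export
insulin_plasma <- function(t_grid, boluses = NULL, basal_rate = 0,
                           tauI1p = 16, tauI2 = 67, tauI3 = 67,
                           S0 = 0, Ip0 = 0) {
  stopifnot(tauI1p > 0, tauI2 > 0, tauI3 > 0)
  t_grid <- as.numeric(t_grid)
  ip <- numeric(length(t_grid))
  if (basal_rate > 0)
    ip <- ip + cpp_chain_step(t_grid, 0, basal_rate, c(tauI1p, tauI2, tauI3))
  if (S0 != 0) {
    ip <- ip + cpp_chain_free(t_grid, S0, tauI1p, c(tauI2, tauI3))
    ip <- ip + cpp_chain_free(t_grid, S0, tauI2, tauI3)
  }
  if (Ip0 != 0) ip <- ip + cpp_chain_free(t_grid, Ip0, tauI3, numeric(0))
  if (!is.null(boluses) && nrow(boluses) > 0) {
    TI <- if ("TI" %in% names(boluses)) boluses$TI else rep(0, nrow(boluses))
    tI1 <- if ("tauI1" %in% names(boluses)) boluses$tauI1 else rep(tauI1p, nrow(boluses))
    IA <- if ("IA" %in% names(boluses)) boluses$IA else rep(1, nrow(boluses))
    if (any(boluses$dose < 0)) stop("bolus dose must be non-negative")
    for (b in seq_len(nrow(boluses))) {
      ip <- ip + cpp_chain_impulse(t_grid, boluses$t_report[b] + TI[b],
                                   IA[b] * boluses$dose[b],
                                   c(tI1[b], tauI2, tauI3))
    }
  }
  ip
}

#' Insulin effect X from injections and the insulin-sensitivity trace
#'
#' The full insulin pathway: [insulin_plasma()] gives `Ip(t)`, and the final
#' first-order stage (time constant `tauI4`) is driven by `SI(t) * Ip(t)`,
#' so the chain has unit DC gain stage by stage and a constant basal rate
#' `u` under constant sensitivity `SI` gives `X -> SI * u`.
#'
#' @inheritParams insulin_plasma
#' @param SI_trace insulin sensitivity evaluated on `t_grid` (recycled if
#'   scalar).
#' @param tauI4 final-stage time constant (min).
#' @param X0 initial insulin effect (1/min).
#' @return numeric vector `X(t)` (1/min).
#' @export
insulin_action <- function(t_grid, boluses = NULL, basal_rate = 0, SI_trace = 0,
                           tauI1p = 16, tauI2 = 67, tauI3 = 67, tauI4 = 24,
                           S0 = 0, Ip0 = 0, X0 = 0) {
  stopifnot(tauI4 > 0)
  ip <- insulin_plasma(t_grid, boluses, basal_rate, tauI1p, tauI2, tauI3, S0, Ip0)
  u <- rep_len(SI_trace, length(t_grid)) * ip
  cpp_first_order_tv(as.numeric(t_grid), u, tauI4, X0)
}

#' Physical-activity effect on insulin sensitivity
#'
#' Each self-reported activity contributes a long-lasting component
#' `P_long * exp(-d / tauP_long)` (non-negative gain) and a short component
#' `P_short * exp(-d / tauP_short)` (signed gain) for `d = t - (t_report +
#' TP) >= 0`; overlapping events superpose additively.
#'
#' @param t_grid evaluation times (min).
#' @param events data.frame with columns `t_report` and optionally `TP`,
#'   `tauP_long`, `tauP_short`, `P_long`, `P_short` (defaults 0, 1040, 45,
#'   0.4, 0).
#' @return numeric vector `PA(t)` (dimensionless sensitivity perturbation).
#' @export
pa_effect <- function(t_grid, events = NULL) {
  t_grid <- as.numeric(t_grid)
  pa <- numeric(length(t_grid))
  if (is.null(events) || nrow(events) == 0) return(pa)
  n <- nrow(events)
  TP <- if ("TP" %in% names(events)) events$TP else rep(0, n)
  tl <- if ("tauP_long" %in% names(events)) events$tauP_long else rep(1040, n)
  ts <- if ("tauP_short" %in% names(events)) events$tauP_short else rep(45, n)
  Pl <- if ("P_long" %in% names(events)) events$P_long else rep(0.4, n)
  Ps <- if ("P_short" %in% names(events)) events$P_short else rep(0, n)
  if (any(tl <= ts)) stop("tauP_long must exceed tauP_short")
  if (any(ts <= 0)) stop("time constants must be positive")
  if (any(Pl < 0)) stop("P_long must be non-negative")
  for (e in seq_len(n)) {
    d <- t_grid - (events$t_report[e] + TP[e])
    on <- d >= 0
    pa[on] <- pa[on] + Pl[e] * exp(-d[on] / tl[e]) + Ps[e] * exp(-d[on] / ts[e])
  }
  pa
}

#' Metabolic-rate signal from heart rate
#'
#' The excess of heart rate over the resting value (clipped at zero) drives
#' two cascaded first-order stages with common time constant `tauE` and unit
#' DC gain; heart rate is held piecewise-constant between readings (for at
#' most `hold_max` minutes, after which the drive falls back to rest).
#'
#' @param t_grid uniform evaluation grid starting at 0 (min).
#' @param hr_t,hr_bpm heart-rate reading times (min) and values (bpm).
#' @param hr_rest resting heart rate (bpm), > 0.
#' @param tauE metabolic time constant (min).
#' @param hold_max maximal hold time of a reading (min).
#' @return numeric vector `E(t)` (bpm excess units).
#' @export
metabolic_rate <- function(t_grid, hr_t, hr_bpm, hr_rest, tauE = 10,
                           hold_max = 15) {
  if (hr_rest <= 0) stop("hr_rest must be positive")
  if (tauE <= 0) stop("tauE must be positive")
  pw <- hr_to_pwc(hr_t, hr_bpm, hr_rest, hold_max)
  cpp_metabolic(as.numeric(t_grid), pw$t, pw$u, tauE, 0, 0)
}

# piecewise-constant clipped excess-HR drive (breakpoint representation)
hr_to_pwc <- function(hr_t, hr_bpm, hr_rest, hold_max = 15) {
  if (length(hr_t) == 0) return(list(t = numeric(0), u = numeric(0)))
  o <- order(hr_t)
  hr_t <- as.numeric(hr_t[o]); hr_bpm <- as.numeric(hr_bpm[o])
  u <- pmax(hr_bpm - hr_rest, 0)
  bt <- hr_t; bu <- u
  gaps <- which(diff(hr_t) > hold_max)
  if (length(gaps)) {
    bt <- c(bt, hr_t[gaps] + hold_max)
    bu <- c(bu, rep(0, length(gaps)))
    o2 <- order(bt)
    bt <- bt[o2]; bu <- bu[o2]
  }
  # final reading also expires
  bt <- c(bt, hr_t[length(hr_t)] + hold_max)
  bu <- c(bu, 0)
  list(t = bt, u = bu)
}

#' Intraday insulin-sensitivity trace
#'
#' `SI(t) = SIE * (1 + PA(t)) * (1 + SIA * sin(2 * pi * (t_day + SIphi)))`
#' with `t_day` the time in days measured from local midnight of the
#' window's calendar day (period fixed at 24 h), so the phase `SIphi`
#' (fraction of a day) is comparable across windows.
#'
#' @param t_grid evaluation times (min from window start).
#' @param SIE mean insulin sensitivity.
#' @param SIA sinusoid amplitude in `[0, 0.5]`.
#' @param SIphi phase (fraction of a day).
#' @param PA physical-activity perturbation on `t_grid` (scalar or vector).
#' @param start_min clock time of the window start (minutes after local
#'   midnight).
#' @return numeric vector `SI(t)`.
#' @export
si_trace <- function(t_grid, SIE, SIA = 0, SIphi = 0, PA = 0, start_min = 0) {
  if (SIA < 0 || SIA > 0.5) stop("SIA must lie in [0, 0.5]")
  td <- (as.numeric(t_grid) + start_min) / 1440 + SIphi
  SIE * (1 + rep_len(PA, length(t_grid))) * (1 + SIA * sin(2 * pi * td))
}

#' Renal glucose excretion (Hovorka-type)
#'
#' `FR = 0.003 * (G - 162)` mg/dL/min above 162 mg/dL, zero below;
#' continuous and piecewise linear in G.
#'
#' @param G blood glucose (mg/dL), scalar or vector.
#' @return excretion rate (mg/dL/min).
#' @export
renal_excretion <- function(G) {
  ifelse(G > 162, 0.003 * (G - 162), 0)
}

#' Glucose and sensor-glucose derivatives
#'
#' The central ODE pair:
#' `dG/dt = -(GEZI + (1 + h) X) G + EGP - SE * E + RA - FR(G)` with
#' `h = H` when `G < Gth` (amplified insulin action in hypoglycemia) and 0
#' otherwise, and the subcutaneous lag `dSG/dt = (G - SG) / tauG`.
#'
#' @param G,SG current blood and subcutaneous glucose (mg/dL).
#' @param X insulin effect (1/min).
#' @param EGP endogenous glucose production (mg/dL/min).
#' @param GEZI glucose effectiveness at zero insulin (1/min).
#' @param SE metabolic-rate gain; `E` metabolic-rate signal.
#' @param RA meal rate of appearance (mg/dL/min).
#' @param H hypoglycemia amplification (>= 0); `Gth` its threshold (mg/dL).
#' @param tauG subcutaneous lag time constant (min).
#' @param E metabolic-rate signal value.
#' @return list with `dG` and `dSG` (mg/dL/min).
#' @export
glucose_rhs <- function(G, SG, X, EGP, GEZI, SE = 0, E = 0, RA = 0,
                        H = 0, Gth = 70, tauG = 15) {
  h <- ifelse(G < Gth, H, 0)
  dG <- -(GEZI + (1 + h) * X) * G + EGP - SE * E + RA - renal_excretion(G)
  dSG <- (G - SG) / tauG
  list(dG = dG, dSG = dSG)
}
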