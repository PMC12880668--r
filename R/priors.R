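#' Prior table for the hierarchical glucose model
#'
#' One row per latent and hierarchy level. Families are truncated normal
#' (`tnorm`), plain normal (`norm`, used for the periodic sinusoid phase),
#' log-normal (`lnorm`, the CGM noise), uniform (`unif`, the cohort phase),
#' exponential (`expo`, estimated spread of several patient-level latents,
#' applied to standard deviations) and half-normal (`halfnorm`, spread of
#' the initial insulin state and of the first bolus time constant).
#'
#' `loc_mode` says where a row's location comes from: a constant (`const`),
#' the same latent one level up (`parent`), or, for the sample-level
#' endogenous glucose production, the linear linkage
#' `EGPi + EGPm * SIE_sample` (`egp`). `scale_mode = "node"` marks rows
#' whose spread is itself estimated (the `s_*` latents). The `source`
#' column flags which numbers are anchored in published T1D estimates
#' versus package defaults tuned so the prior predictive spans the
#' physiological 0-400 mg/dL band.
#'
#' Units: minutes, mg/dL, grams, insulin units; insulin sensitivity is per
#' U/min of chain output (no plasma volume is modelled, so the uU/mL
#' conversion is folded into SI).
#'
#' @return data.frame of class `vp_priors`.
#' @export
vp_priors <- function() {
  r <- function(latent, level, family, loc_mode, loc, scale_mode, scale,
                lower, upper, slot, fd, source = "default",
                scale_node = NA_character_)
    data.frame(latent = latent, level = level, family = family,
               loc_mode = loc_mode, loc = loc, scale_mode = scale_mode,
               scale = scale, lower = lower, upper = upper, slot = slot,
               fd = fd, source = source, scale_node = scale_node,
               stringsAsFactors = FALSE)
  tab <- rbind(
    # --- glucose-side physiology (cohort -> patient) ---
    r("VG",    "cohort",  "tnorm", "const", 120,    "const", 30,    30,   300,  TRUE,  0.05),
    r("VG",    "patient", "tnorm", "parent", NA,    "const", 15,    30,   300,  TRUE,  0.05),
    r("GEZI",  "cohort",  "tnorm", "const", 2.5e-3, "const", 1.5e-3, 1e-3, 1e-2, TRUE, 1e-6, "literature"),
    r("GEZI",  "patient", "tnorm", "parent", NA,    "const", 1e-3,  1e-3, 1e-2, TRUE, 1e-6, "literature"),
    r("EGPi",  "cohort",  "tnorm", "const", 1.0,    "const", 0.5,   0,    3.5,  TRUE,  1e-4, "literature"),
    r("EGPi",  "patient", "tnorm", "parent", NA,    "const", 0.35,  0,    3.5,  TRUE,  1e-4),
    r("EGPm",  "patient", "tnorm", "const", 2,      "const", 2,     -5,   12,   TRUE,  1e-3),
    r("s_EGP", "patient", "expo",  "const", 0.3,    "const", NA,    0,    Inf,  FALSE, 1e-3),
    r("EGP",   "sample",  "tnorm", "egp",    NA,    "node",  NA,    0,    5,    TRUE,  1e-4,
      scale_node = "s_EGP"),
    # --- insulin sensitivity and its intraday modulation ---
    r("SIE",   "cohort",  "tnorm", "const", 0.3,    "const", 0.15,  0.01, 1.5,  TRUE,  1e-4),
    r("SIE",   "patient", "tnorm", "parent", NA,    "const", 0.08,  0.01, 1.5,  TRUE,  1e-4),
    r("s_SIE", "patient", "expo",  "const", 0.05,   "const", NA,    0,    Inf,  FALSE, 1e-4),
    r("SIE",   "sample",  "tnorm", "parent", NA,    "node",  NA,    0.01, 1.5,  TRUE,  1e-4,
      scale_node = "s_SIE"),
    r("SIA",   "cohort",  "tnorm", "const", 0.2,    "const", 0.1,   0,    0.5,  TRUE,  1e-4, "literature"),
    r("SIA",   "patient", "tnorm", "parent", NA,    "const", 0.06,  0,    0.5,  TRUE,  1e-4, "literature"),
    r("s_SIA", "patient", "expo",  "const", 0.05,   "const", NA,    0,    Inf,  FALSE, 1e-4),
    r("SIA",   "sample",  "tnorm", "parent", NA,    "node",  NA,    0,    0.5,  TRUE,  1e-4,
      scale_node = "s_SIA"),
    r("SIphi", "cohort",  "unif",  "const", 0,      "const", NA,    0,    1,    TRUE,  1e-4),
    r("SIphi", "patient", "norm",  "parent", NA,    "const", 0.08,  -Inf, Inf,  TRUE,  1e-4),
    r("s_SIphi", "patient", "expo", "const", 0.06,  "const", NA,    0,    Inf,  FALSE, 1e-4),
    r("SIphi", "sample",  "norm",  "parent", NA,    "node",  NA,    -Inf, Inf,  TRUE,  1e-4,
      scale_node = "s_SIphi"),
    # --- CGM measurement noise (nested log-normal) ---
    r("sigma", "cohort",  "lnorm", "const", log(12), "const", 0.4,  0,    Inf,  TRUE,  1e-3, "literature"),
    r("sigma", "patient", "lnorm", "parent", NA,     "const", 0.25, 0,    Inf,  TRUE,  1e-3),
    r("sigma", "sample",  "lnorm", "parent", NA,     "const", 0.2,  0,    Inf,  TRUE,  1e-3),
    # --- sensing and insulin kinetics ---
    r("tauG",  "cohort",  "tnorm", "const", 15,     "const", 6,     5,    30,   TRUE,  2e-3, "literature"),
    r("tauG",  "patient", "tnorm", "parent", NA,    "const", 4,     5,    30,   TRUE,  2e-3, "literature"),
    r("s_tauI1", "cohort", "halfnorm", "const", 0,  "const", 8,     0,    Inf,  FALSE, 2e-3),
    r("tauI1", "patient", "tnorm", "const", 16,     "node",  NA,    3,    60,   TRUE,  2e-3, "literature",
      scale_node = "s_tauI1"),
    r("tauI1", "bolus",   "tnorm", "parent", NA,    "const", 4,     3,    60,   TRUE,  2e-3, "literature"),
    r("tauI2", "cohort",  "tnorm", "const", 60,     "const", 20,    20,   120,  TRUE,  2e-3, "literature"),
    r("tauI2", "patient", "tnorm", "parent", NA,    "const", 10,    20,   120,  TRUE,  2e-3, "literature"),
    r("tauI3", "cohort",  "tnorm", "const", 60,     "const", 20,    20,   120,  TRUE,  2e-3, "literature"),
    r("tauI3", "patient", "tnorm", "parent", NA,    "const", 10,    20,   120,  TRUE,  2e-3, "literature"),
    r("tauI4", "cohort",  "tnorm", "const", 30,     "const", 12,    5,    90,   TRUE,  2e-3, "literature"),
    r("tauI4", "patient", "tnorm", "parent", NA,    "const", 8,     5,    90,   TRUE,  2e-3, "literature"),
    # --- metabolic-rate (heart-rate) pathway ---
    r("tauE",  "cohort",  "tnorm", "const", 10,     "const", 6,     1,    60,   TRUE,  2e-3),
    r("tauE",  "patient", "tnorm", "parent", NA,    "const", 3,     1,    60,   TRUE,  2e-3),
    r("SE",    "cohort",  "tnorm", "const", 0.01,   "const", 0.008, 0,    0.05, TRUE,  1e-5),
    r("SE",    "patient", "tnorm", "parent", NA,    "const", 0.004, 0,    0.05, TRUE,  1e-5),
    # --- hypoglycemia amplification ---
    r("H",     "cohort",  "tnorm", "const", 0.3,    "const", 0.4,   0,    2,    TRUE,  1e-3),
    r("H",     "patient", "tnorm", "parent", NA,    "const", 0.2,   0,    2,    TRUE,  1e-3),
    r("Gth",   "cohort",  "tnorm", "const", 70,     "const", 8,     50,   90,   TRUE,  2e-3),
    r("Gth",   "patient", "tnorm", "parent", NA,    "const", 4,     50,   90,   TRUE,  2e-3),
    # --- initial insulin state (cohort -> patient -> sample) ---
    r("s_X0",  "cohort",  "halfnorm", "const", 0,   "const", 0.004, 0,    Inf,  FALSE, 1e-5),
    r("X0",    "cohort",  "tnorm", "const", 0.008,  "const", 0.005, 0,    0.05, TRUE,  1e-5),
    r("X0",    "patient", "tnorm", "parent", NA,    "node",  NA,    0,    0.05, TRUE,  1e-5,
      scale_node = "s_X0"),
    r("X0",    "sample",  "tnorm", "parent", NA,    "const", 0.003, 0,    0.05, TRUE,  1e-5),
    r("S0",    "cohort",  "tnorm", "const", 0.015,  "const", 0.008, 0,    0.1,  TRUE,  1e-5),
    r("S0",    "patient", "tnorm", "parent", NA,    "const", 0.004, 0,    0.1,  TRUE,  1e-5),
    r("S0",    "sample",  "tnorm", "parent", NA,    "const", 0.004, 0,    0.1,  TRUE,  1e-5),
    r("Ip0",   "cohort",  "tnorm", "const", 0.015,  "const", 0.008, 0,    0.1,  TRUE,  1e-5),
    r("Ip0",   "patient", "tnorm", "parent", NA,    "const", 0.004, 0,    0.1,  TRUE,  1e-5),
    r("Ip0",   "sample",  "tnorm", "parent", NA,    "const", 0.004, 0,    0.1,  TRUE,  1e-5),
    # --- meal absorption ---
    r("s_tauD1", "cohort", "expo", "const", 2,      "const", NA,    0,    Inf,  FALSE, 2e-3),
    r("tauD1", "patient", "tnorm", "const", 5,      "node",  NA,    1,    10,   TRUE,  2e-3, "literature",
      scale_node = "s_tauD1"),
    r("tauD2", "patient", "tnorm", "const", 48,     "const", 15,    15,   120,  TRUE,  2e-3, "literature"),
    r("tauD2", "meal",    "tnorm", "parent", NA,    "const", 10,    15,   120,  TRUE,  2e-3, "literature"),
    r("TD",    "meal",    "tnorm", "const", 15,     "const", 15,    -30,  90,   TRUE,  2e-3, "literature"),
    r("MA",    "meal",    "tnorm", "const", 1,      "const", 0.2,   0.1,  3,    TRUE,  1e-4, "literature"),
    # --- bolus events ---
    r("TI",    "bolus",   "tnorm", "const", 5,      "const", 10,    -30,  60,   TRUE,  2e-3),
    r("IA",    "bolus",   "tnorm", "const", 1,      "const", 0.2,   0.1,  3,    TRUE,  1e-4),
    # --- physical activity ---
    r("s_tauPl", "cohort", "expo", "const", 300,    "const", NA,    0,    Inf,  FALSE, 0.1),
    r("tauP_long", "patient", "tnorm", "const", 1040, "node", NA,   130,  3000, TRUE,  0.1, "literature",
      scale_node = "s_tauPl"),
    r("tauP_long", "exercise", "tnorm", "parent", NA, "const", 150, 130,  3000, TRUE,  0.1, "literature"),
    r("tauP_short", "patient", "tnorm", "const", 45, "const", 25,   5,    120,  TRUE,  2e-3, "literature"),
    r("tauP_short", "exercise", "tnorm", "parent", NA, "const", 15, 5,    120,  TRUE,  2e-3, "literature"),
    r("TP",    "exercise", "tnorm", "const", 10,    "const", 15,    -60,  120,  TRUE,  2e-3, "literature"),
    r("P_long", "exercise", "tnorm", "const", 0.4,  "const", 0.3,   0,    2,    TRUE,  1e-4, "literature"),
    r("P_short", "exercise", "tnorm", "const", 0,   "const", 0.25,  -0.8, 1.5,  TRUE,  1e-4))
  class(tab) <- c("vp_priors", "data.frame")
  tab
}

#' Write / read the effective prior table
#'
#' Round-trips the prior table through a plain CSV, preserving the
#' provenance flags.
#'
#' @param priors a [vp_priors()] table.
#' @param file path to a CSV file.
#' @export
write_priors <- function(priors, file) {
  write.csv(as.data.frame(priors), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_priors
#' @export
read_priors <- function(file) {
  tab <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("latent", "level", "family", "loc_mode", "loc", "scale_mode",
            "scale", "lower", "upper", "slot", "fd", "source", "scale_node")
  if (!all(need %in% names(tab))) stop("not a prior table: missing columns")
  tab <- tab[, need]
  class(tab) <- c("vp_priors", "data.frame")
  tab
}

# ---- distribution helpers (constrained space) ------------------------------

# truncated normal on [l, u]
dtnorm <- function(x, mean, sd, l, u, log = TRUE) {
  lz <- dnorm(x, mean, sd, log = TRUE) -
    log(pnorm(u, mean, sd) - pnorm(l, mean, sd))
  lz[x < l | x > u] <- -Inf
  if (log) lz else exp(lz)
}

rtnorm <- function(n, mean, sd, l, u) {
  if (any(sd < 0)) stop("sd must be non-negative")
  pl <- pnorm(l, mean, sd); pu <- pnorm(u, mean, sd)
  q <- qnorm(pl + runif(n) * (pu - pl), mean, sd)
  pmin(pmax(q, l), u)
}

dhalfnorm <- function(x, scale, log = TRUE) {
  lz <- ifelse(x < 0, -Inf, log(2) + dnorm(x, 0, scale, log = TRUE))
  if (log) lz else exp(lz)
}

# exponential parameterized by its MEAN
dexpo <- function(x, mean, log = TRUE) {
  dexp(x, rate = 1 / mean, log = log)
}
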