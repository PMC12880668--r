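# Posterior-predictive simulation with intraday / interday variability
# resampling: the "stochastic virtual population" side of a fitted model.

# redraw a window's variability latents from its patient-level laws,
# given the rest of the latent vector
resample_window_latents <- function(z, nodes, s, mode) {
  if (mode == "none") return(z)
  p <- nodes$hier$sample_patient[s]
  sid <- nodes$sample_ids; pid <- nodes$patient_ids
  draw_tn <- function(m, sc, l, u) rtnorm(1, m, sc, l, u)
  # intraday: amplitude and phase of the sinusoid
  z[sid[["SIA"]][s]] <- draw_tn(z[pid[["SIA"]][p]], z[pid[["s_SIA"]][p]], 0, 0.5)
  z[sid[["SIphi"]][s]] <- rnorm(1, z[pid[["SIphi"]][p]], z[pid[["s_SIphi"]][p]])
  if (mode == "interday") {
    tab <- nodes$table
    i <- sid[["SIE"]][s]
    z[i] <- draw_tn(z[pid[["SIE"]][p]], z[pid[["s_SIE"]][p]],
                    tab$lower[i], tab$upper[i])
    j <- sid[["EGP"]][s]
    z[j] <- draw_tn(z[pid[["EGPi"]][p]] + z[pid[["EGPm"]][p]] * z[i],
                    z[pid[["s_EGP"]][p]], tab$lower[j], tab$upper[j])
  }
  z
}

#' Posterior-predictive trajectory ensembles
#'
#' Simulates each window under `n` posterior draws, with the observed
#' events, insulin and heart rate held fixed. `resample = "intraday"`
#' replaces each draw's window-level sinusoid amplitude and phase with
#' fresh draws from the fitted patient-level distribution (new diurnal
#' variability for the same day); `"interday"` additionally redraws the
#' window's insulin sensitivity and, through the fitted linear linkage,
#' its endogenous glucose production (a new day for that patient).
#'
#' @param fit an [fit_svi()] result carrying nodes (e.g. from [vp_fit()]).
#' @param samples the windows the fit was built on.
#' @param n posterior draws per window.
#' @param seed RNG seed.
#' @param resample `"none"`, `"intraday"` or `"interday"`.
#' @param windows integer subset of windows (default all).
#' @param cgm_noise add CGM measurement noise (the draw's own sigma) to
#'   the simulated sensor glucose.
#' @param grid_dt simulation step (min).
#' @return list of class `vp_predictive`: per window, a list with `t`,
#'   `SG` (matrix with `n` columns) and the window index; failed
#'   integrations are returned as `NA` columns.
#' @export
posterior_predictive <- function(fit, samples, n = 100, seed = 1,
                                 resample = c("none", "intraday", "interday"),
                                 windows = NULL, cgm_noise = FALSE,
                                 grid_dt = 5) {
  resample <- match.arg(resample)
  nodes <- fit$nodes
  if (is.null(nodes)) stop("fit carries no node table")
  draws <- sample_posterior(fit, n, seed)
  ed <- prepare_engine_data(samples)
  if (is.null(windows)) windows <- seq_along(samples)
  out <- lapply(windows, function(s) {
    nt <- as.integer(round(samples[[s]]$t_end / grid_dt)) + 1L
    SG <- matrix(NA_real_, nt, n)
    for (j in seq_len(n)) {
      z <- resample_window_latents(draws$z[, j], nodes, s, resample)
      o <- simulate_from_latents(z, nodes, ed, s, grid_dt)
      if (o$ok) {
        sg <- o$SG
        if (cgm_noise)
          sg <- sg + rnorm(length(sg), 0, z[nodes$sample_ids[["sigma"]][s]])
        SG[, j] <- sg
      }
    }
    list(window = s, t = seq(0, samples[[s]]$t_end, by = grid_dt), SG = SG)
  })
  names(out) <- as.character(windows)
  structure(out, class = "vp_predictive")
}

# posterior-predictive mean SG at given times, per window
predictive_mean_at <- function(pp, times_list) {
  lapply(seq_along(pp), function(k) {
    m <- rowMeans(pp[[k]]$SG, na.rm = TRUE)
    approx(pp[[k]]$t, m, xout = times_list[[k]])$y
  })
}
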