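#' Fit a stochastic virtual population to a cohort of 24h windows
#'
#' The main modelling entry point: builds the four-level hierarchical
#' model over the supplied windows and fits it by stochastic variational
#' inference ([fit_svi()]) with a low-rank multivariate normal guide. The
#' returned object supports `print`, `summary`, `coef`, `fitted`,
#' `residuals`, `predict`, `simulate` and `plot`.
#'
#' @param samples list of [sample24h()] windows in patient-major order
#'   (e.g. from [process_records()] or [generate_cohort()]).
#' @param priors a [vp_priors()] table.
#' @param control an [svi_config()]; defaults mirror the reference setup
#'   (15 particles, 80,000 iterations). Scale these down for exploratory
#'   fits.
#' @param patient_ids optional patient per window.
#' @param grid_dt likelihood simulation step (min).
#' @return object of class `vp_fit`.
#' @export
vp_fit <- function(samples, priors = vp_priors(), control = svi_config(),
                   patient_ids = NULL, grid_dt = 5) {
  model <- vp_model(samples, priors, patient_ids = patient_ids,
                    grid_dt = grid_dt)
  fit <- fit_svi(model, control)
  structure(list(svi = fit, guide = fit$guide, elbo = fit$elbo,
                 nodes = model$nodes, samples = samples, model = model,
                 control = control, call = match.call()),
            class = "vp_fit")
}

#' @export
print.vp_fit <- function(x, ...) {
  h <- x$nodes$hier
  cat(sprintf("Stochastic virtual population: %d patients, %d windows, %d latent nodes\n",
              h$n_patients, length(h$sample_patient), nrow(x$nodes$table)))
  cat(sprintf("SVI: rank-%d MVN guide, %d iterations, final ELBO %.1f\n",
              x$guide$r, length(x$elbo),
              mean(tail(x$elbo, max(1, length(x$elbo) %/% 50)))))
  invisible(x)
}

#' @export
coef.vp_fit <- function(object, level = c("cohort", "patient", "sample"),
                        n = 500, seed = 1, ...) {
  level <- match.arg(level)
  draws <- sample_posterior(object$svi, n, seed)
  tab <- object$nodes$table
  i <- tab$level == level
  mu <- rowMeans(draws$z[i, , drop = FALSE])
  setNames(mu, tab$name[i])
}

#' @export
summary.vp_fit <- function(object, n = 500, seed = 1, ...) {
  draws <- sample_posterior(object$svi, n, seed)
  tab <- object$nodes$table
  qs <- function(i) {
    z <- draws$z[i, , drop = FALSE]
    data.frame(node = tab$name[i], mean = rowMeans(z),
               ci_lo = apply(z, 1, quantile, 0.025),
               ci_hi = apply(z, 1, quantile, 0.975), row.names = NULL)
  }
  out <- list(cohort = qs(which(tab$level == "cohort")),
              patient_sie_egp = NULL, elbo = object$elbo)
  pid <- object$nodes$patient_ids
  h <- object$nodes$hier
  rows <- lapply(seq_len(h$n_patients), function(p) {
    sie <- draws$z[pid[["SIE"]][p], ]
    # per-window EGP pooled over this patient's windows
    ws <- which(h$sample_patient == p)
    egp <- as.vector(draws$z[object$nodes$sample_ids[["EGP"]][ws], , drop = FALSE])
    data.frame(patient = p, SIE = mean(sie),
               SIE_lo = quantile(sie, 0.025), SIE_hi = quantile(sie, 0.975),
               EGP = mean(egp), EGP_lo = quantile(egp, 0.025),
               EGP_hi = quantile(egp, 0.975), row.names = NULL)
  })
  out$patient_sie_egp <- do.call(rbind, rows)
  class(out) <- "summary.vp_fit"
  out
}

#' @export
print.summary.vp_fit <- function(x, ...) {
  cat("Cohort-level posterior (mean and 95% interval):\n")
  print(x$cohort, digits = 3)
  cat("\nPatient-level insulin sensitivity and EGP:\n")
  print(x$patient_sie_egp, digits = 3)
  invisible(x)
}

#' @export
fitted.vp_fit <- function(object, n = 100, seed = 1, ...) {
  pp <- posterior_predictive(object$svi, object$samples, n = n, seed = seed)
  predictive_mean_at(pp, lapply(object$samples, function(s) s$cgm$t))
}

#' @export
residuals.vp_fit <- function(object, n = 100, seed = 1, ...) {
  mu <- fitted(object, n = n, seed = seed)
  lapply(seq_along(mu), function(s) object$samples[[s]]$cgm$glucose - mu[[s]])
}

#' Posterior-predictive prediction from a fitted virtual population
#'
#' `type = "mean"` returns the posterior-predictive mean sensor-glucose
#' trace per window; `type = "draws"` the full trajectory ensembles.
#'
#' @param object a [vp_fit()].
#' @param type `"mean"` or `"draws"`.
#' @param n draws; `seed` RNG seed; `windows` subset; `resample`
#'   variability mode, see [posterior_predictive()].
#' @param ... unused.
#' @export
predict.vp_fit <- function(object, type = c("mean", "draws"), n = 100,
                           seed = 1, windows = NULL, resample = "none", ...) {
  type <- match.arg(type)
  pp <- posterior_predictive(object$svi, object$samples, n = n, seed = seed,
                             resample = resample, windows = windows)
  if (type == "draws") return(pp)
  lapply(pp, function(w) list(t = w$t, SG = rowMeans(w$SG, na.rm = TRUE)))
}

#' Simulate new virtual days from a fitted population
#'
#' A thin wrapper over [posterior_predictive()] with interday resampling:
#' each simulation is a fresh plausible day for the window's patient.
#'
#' @param object a [vp_fit()].
#' @param nsim simulations per window.
#' @param seed RNG seed.
#' @param resample variability mode (default `"interday"`).
#' @param ... passed to [posterior_predictive()].
#' @export
simulate.vp_fit <- function(object, nsim = 1, seed = 1,
                            resample = "interday", ...) {
  posterior_predictive(object$svi, object$samples, n = nsim, seed = seed,
                       resample = resample, ...)
}

#' Plot a fitted window
#'
#' CGM readings, the posterior-predictive mean sensor glucose and its
#' 10-90 percentile band.
#'
#' @param x a [vp_fit()].
#' @param window window index.
#' @param n posterior draws.
#' @param seed RNG seed.
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.vp_fit <- function(x, window = 1, n = 100, seed = 1, ...) {
  pp <- posterior_predictive(x$svi, x$samples, n = n, seed = seed,
                             windows = window)[[1]]
  s <- x$samples[[window]]
  q <- apply(pp$SG, 1, quantile, probs = c(0.1, 0.5, 0.9), na.rm = TRUE)
  graphics::plot(s$cgm$t / 60, s$cgm$glucose, pch = 16, cex = 0.4,
                 xlab = "hours", ylab = "glucose (mg/dL)",
                 ylim = range(c(s$cgm$glucose, q), na.rm = TRUE), ...)
  graphics::polygon(c(pp$t, rev(pp$t)) / 60, c(q[1, ], rev(q[3, ])),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(pp$t / 60, rowMeans(pp$SG, na.rm = TRUE), col = "black",
                  lwd = 2, lty = 2)
  invisible(x)
}
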