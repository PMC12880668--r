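# Results analytics: posterior-predictive RMSE, glycemic metrics under
# variability replay, peak-sensitivity period fractions, next-hour
# prediction scenarios, and the post-hoc meal regressions.

#' Glycemic metrics of a glucose trace
#'
#' Time-average glucose and the time-in/below/above-range partition of a
#' uniformly sampled trace. The three percentages sum to 100 exactly.
#'
#' @param g glucose values on a uniform grid (mg/dL).
#' @param lo,hi target-range thresholds (mg/dL); 70-180 consensus default.
#' @return data.frame with `mean_bg`, `tir`, `tbr`, `tar` (percent).
#' @export
glycemic_metrics <- function(g, lo = 70, hi = 180) {
  g <- g[!is.na(g)]
  tbr <- 100 * mean(g < lo)
  tar <- 100 * mean(g > hi)
  data.frame(mean_bg = mean(g), tir = 100 - tbr - tar, tbr = tbr, tar = tar)
}

#' Posterior-predictive RMSE per patient
#'
#' Per window: root-mean-square error between the CGM readings and the
#' mean of the posterior-predictive sensor glucose at the CGM timestamps.
#' Per patient: the mean over that patient's windows, with a 95%
#' nonparametric bootstrap CI over windows.
#'
#' @param fit,samples as in [posterior_predictive()].
#' @param n posterior draws for the predictive mean.
#' @param seed RNG seed.
#' @param n_boot bootstrap resamples.
#' @return list with `by_window` and `by_patient` data.frames.
#' @export
rmse_posterior_mean <- function(fit, samples, n = 100, seed = 1,
                                n_boot = 10000) {
  pp <- posterior_predictive(fit, samples, n = n, seed = seed)
  keep <- vapply(samples, function(s) nrow(s$cgm) > 0, TRUE)
  if (any(!keep)) warning(sprintf("%d window(s) without CGM excluded", sum(!keep)))
  mu <- predictive_mean_at(pp, lapply(samples, function(s) s$cgm$t))
  rmse <- vapply(which(keep), function(s)
    sqrt(mean((samples[[s]]$cgm$glucose - mu[[s]])^2)), 0)
  pid <- vapply(samples, function(s) as.character(s$patient_id), "")[keep]
  by_window <- data.frame(window = which(keep), patient_id = pid, rmse = rmse)
  by_patient <- do.call(rbind, lapply(unique(pid), function(id) {
    x <- rmse[pid == id]
    bm <- replicate(n_boot, mean(sample(x, replace = TRUE)))
    data.frame(patient_id = id, rmse = mean(x),
               ci_lo = as.numeric(quantile(bm, 0.025)),
               ci_hi = as.numeric(quantile(bm, 0.975)), n_windows = length(x))
  }))
  list(by_window = by_window, by_patient = by_patient)
}

#' Glycemic metrics under variability replay
#'
#' Compares, per patient, the glycemic metrics of the measured CGM with
#' those of posterior-predictive ensembles under intraday resampling and
#' (optionally) combined intra- and interday resampling, and returns the
#' per-window 10-90 percentile trajectory bands.
#'
#' @param fit,samples,n,seed,grid_dt as in [posterior_predictive()].
#' @param mode `"intraday"` for intraday only, `"interday"` for both.
#' @param lo,hi range thresholds (mg/dL).
#' @return list with `metrics` (one row per patient and source) and
#'   `bands` (per window: `t`, `lo`, `hi` matrices by mode).
#' @export
replay_variability <- function(fit, samples, mode = c("interday", "intraday"),
                               n = 100, seed = 1, lo = 70, hi = 180,
                               grid_dt = 5) {
  mode <- match.arg(mode)
  modes <- if (mode == "interday") c("intraday", "interday") else "intraday"
  pid <- vapply(samples, function(s) as.character(s$patient_id), "")
  pp <- lapply(modes, function(m)
    posterior_predictive(fit, samples, n = n, seed = seed, resample = m,
                         cgm_noise = TRUE, grid_dt = grid_dt))
  names(pp) <- modes
  rows <- list()
  for (id in unique(pid)) {
    w <- which(pid == id)
    cgm_all <- unlist(lapply(samples[w], function(s) s$cgm$glucose))
    rows[[length(rows) + 1]] <- cbind(patient_id = id, source = "cgm",
                                      glycemic_metrics(cgm_all, lo, hi))
    for (m in modes) {
      sim_all <- unlist(lapply(w, function(s) pp[[m]][[as.character(s)]]$SG))
      rows[[length(rows) + 1]] <- cbind(patient_id = id, source = m,
                                        glycemic_metrics(sim_all, lo, hi))
    }
  }
  bands <- lapply(seq_along(samples), function(s) {
    b <- lapply(modes, function(m) {
      q <- apply(pp[[m]][[as.character(s)]]$SG, 1, quantile,
                 probs = c(0.1, 0.9), na.rm = TRUE)
      list(lo = q[1, ], hi = q[2, ])
    })
    names(b) <- modes
    c(list(t = pp[[modes[1]]][[as.character(s)]]$t), b)
  })
  list(metrics = do.call(rbind, rows), bands = bands)
}

#' Daily period of peak insulin sensitivity
#'
#' For each posterior draw and window, locates the clock time at which the
#' intraday sinusoid peaks (`t_day = (1/4 - phase) mod 1`) and bins it
#' into breakfast (2-10 h), lunch (10-18 h) and dinner (18-2 h, wrapping
#' midnight). Draws with amplitude below `eps` have no unique argmax and
#' are excluded (their count is reported).
#'
#' @param fit a fitted model carrying nodes.
#' @param n posterior draws.
#' @param seed RNG seed.
#' @param eps amplitude below which a draw is treated as degenerate.
#' @return list with `by_patient` (B/L/D percentages summing to 100) and
#'   `n_degenerate`.
#' @export
peak_si_fractions <- function(fit, n = 200, seed = 1, eps = 1e-6) {
  nodes <- fit$nodes
  draws <- sample_posterior(fit, n, seed)
  sid <- nodes$sample_ids
  S <- length(nodes$hier$sample_patient)
  pat <- nodes$hier$sample_patient
  counts <- matrix(0, nodes$hier$n_patients, 3,
                   dimnames = list(NULL, c("B", "L", "D")))
  n_deg <- 0L
  for (s in seq_len(S)) {
    sia <- draws$z[sid[["SIA"]][s], ]
    phi <- draws$z[sid[["SIphi"]][s], ]
    ok <- sia > eps
    n_deg <- n_deg + sum(!ok)
    h <- 24 * ((0.25 - phi[ok]) %% 1)
    bin <- ifelse(h > 2 & h <= 10, 1L, ifelse(h > 10 & h <= 18, 2L, 3L))
    for (b in 1:3) counts[pat[s], b] <- counts[pat[s], b] + sum(bin == b)
  }
  tot <- rowSums(counts)
  by_patient <- data.frame(patient = seq_len(nrow(counts)),
                           100 * counts / ifelse(tot == 0, 1, tot))
  list(by_patient = by_patient, n_degenerate = n_deg)
}

#' Prediction-scenario definitions
#'
#' Blanking windows (min) before a prediction origin within which the
#' effect of meals, insulin and physical activity is treated as unknown
#' (scenarios 1-2) or required to be absent (scenario 3).
#'
#' @param id scenario 1, 2 or 3.
#' @return list of class `prediction_scenario`.
#' @export
prediction_scenario <- function(id) {
  blank <- switch(as.character(id),
                  "1" = c(meal = 45, insulin = 120, activity = 1440),
                  "2" = c(meal = 30, insulin = 45, activity = 45),
                  "3" = c(meal = 45, insulin = 120, activity = 1440),
                  stop("scenario id must be 1, 2 or 3"))
  structure(list(id = as.integer(id), blank = blank,
                 require_absent = id == 3, horizons = c(30, 60)),
            class = "prediction_scenario")
}

#' Next-hour blood-glucose prediction error
#'
#' At origins every `origin_step` minutes within each window, simulates
#' forward under posterior draws (window EGP and insulin sensitivity
#' redrawn from the patient-level posterior law), anchors the predicted
#' sensor-glucose increment at the measured CGM value at the origin, and
#' pools the RMSE against CGM at each horizon. Under scenarios 1-2 the
#' events inside the blanking windows before the origin are dropped
#' (their effect is unknown to the predictor); under scenario 3 only
#' origins with no such events at all are eligible.
#'
#' @param fit,samples fitted model and its windows.
#' @param scenario a [prediction_scenario()] or its id.
#' @param n posterior draws per origin.
#' @param seed RNG seed.
#' @param origin_step origin spacing (min).
#' @param grid_dt simulation step (min).
#' @return data.frame with `horizon`, `rmse`, `n_origins` (empty when no
#'   origin is eligible).
#' @export
prediction_eval <- function(fit, samples, scenario, n = 20, seed = 1,
                            origin_step = 30, grid_dt = 5) {
  if (!inherits(scenario, "prediction_scenario"))
    scenario <- prediction_scenario(scenario)
  nodes <- fit$nodes
  draws <- sample_posterior(fit, n, seed)
  hz <- scenario$horizons
  bl <- scenario$blank
  err <- vector("list", length(hz)); names(err) <- as.character(hz)
  n_orig <- 0L
  for (s in seq_along(samples)) {
    smp <- samples[[s]]
    cgm <- smp$cgm
    origins <- seq(origin_step, smp$t_end - max(hz), by = origin_step)
    for (o in origins) {
      in_blank <- function(t, w) t > o - w & t <= o
      nm_bl <- in_blank(smp$meals$t, bl["meal"])
      nb_bl <- in_blank(smp$boluses$t, bl["insulin"])
      ne_bl <- in_blank(smp$exercise$t, bl["activity"])
      if (scenario$require_absent && (any(nm_bl) || any(nb_bl) || any(ne_bl)))
        next
      # the predictor only knows events outside the blanking windows and
      # nothing after the origin
      smp2 <- smp
      smp2$meals <- smp$meals[!nm_bl & smp$meals$t <= o, , drop = FALSE]
      smp2$boluses <- smp$boluses[!nb_bl & smp$boluses$t <= o, , drop = FALSE]
      smp2$exercise <- smp$exercise[!ne_bl & smp$exercise$t <= o, , drop = FALSE]
      # window layout changed: map onto the original slots by masking
      # dropped events instead of rebuilding the hierarchy
      keep_m <- which(!nm_bl & smp$meals$t <= o)
      keep_b <- which(!nb_bl & smp$boluses$t <= o)
      keep_e <- which(!ne_bl & smp$exercise$t <= o)
      ed <- as_engine_data(smp2)
      y_o <- approx(cgm$t, cgm$glucose, xout = o, rule = 2)$y
      pred <- matrix(NA_real_, length(hz), n)
      for (j in seq_len(n)) {
        z <- resample_window_latents(draws$z[, j], nodes, s, "interday")
        slots <- z[nodes$slot_map[[s]]]
        slots <- mask_event_slots(slots, nodes$hier, s, keep_m, keep_b, keep_e)
        sim <- cpp_simulate(slots, ed, grid_dt, "analytic_fast", 0.25)
        if (!sim$ok) next
        sg_o <- approx(sim$t, sim$SG, xout = o)$y
        for (k in seq_along(hz)) {
          sg_h <- approx(sim$t, sim$SG, xout = o + hz[k])$y
          pred[k, j] <- y_o + (sg_h - sg_o)
        }
      }
      mu <- rowMeans(pred, na.rm = TRUE)
      if (any(!is.finite(mu))) next
      n_orig <- n_orig + 1L
      for (k in seq_along(hz)) {
        y_h <- approx(cgm$t, cgm$glucose, xout = o + hz[k], rule = 2)$y
        err[[k]] <- c(err[[k]], (y_h - mu[k])^2)
      }
    }
  }
  if (n_orig == 0L)
    return(data.frame(horizon = hz, rmse = NA_real_, n_origins = 0L))
  data.frame(horizon = hz,
             rmse = vapply(err, function(e) sqrt(mean(e)), 0),
             n_origins = n_orig)
}

# keep only selected events' slots (header stays; dropped events removed)
mask_event_slots <- function(slots, hier, s, keep_m, keep_b, keep_e) {
  nm <- hier$n_meals[s]; nb <- hier$n_boluses[s]; ne <- hier$n_exercise[s]
  idx <- c(seq_len(20),
           20 + as.vector(vapply(keep_m, function(m) (m - 1) * 3 + 1:3, numeric(3))),
           20 + 3 * nm + as.vector(vapply(keep_b, function(b) (b - 1) * 3 + 1:3, numeric(3))),
           20 + 3 * nm + 3 * nb + as.vector(vapply(keep_e, function(e) (e - 1) * 5 + 1:5, numeric(5))))
  slots[idx]
}

#' Post-hoc regression of meal parameters on meal composition
#'
#' Ordinary least squares of the posterior means of each meal-level
#' parameter (absorption time constant, start offset, meal coefficient)
#' on the meal's carbohydrate, fat and protein content and on `dCGM`, the
#' measured glucose at the reported meal time minus 40 mg/dL.
#'
#' @param fit,samples fitted model and its windows.
#' @param n posterior draws used for the posterior means.
#' @param seed RNG seed.
#' @return list of class `meal_ols` with one coefficient table
#'   (`coef`, `p`, `ci_lo`, `ci_hi`) per parameter and the assembled
#'   per-meal data.
#' @export
posthoc_meal_regression <- function(fit, samples, n = 200, seed = 1) {
  nodes <- fit$nodes
  draws <- sample_posterior(fit, n, seed)
  zbar <- rowMeans(draws$z)
  tab <- nodes$table
  rows <- list()
  for (s in seq_along(samples)) {
    smp <- samples[[s]]
    if (nrow(smp$meals) == 0) next
    for (m in seq_len(nrow(smp$meals))) {
      nm <- sprintf(".s%d.m%d", s, m)
      gi <- function(l) zbar[which(tab$latent == l & tab$name ==
                                     paste0(l, nm))]
      y_cgm <- approx(smp$cgm$t, smp$cgm$glucose, xout = smp$meals$t[m],
                      rule = 2)$y
      rows[[length(rows) + 1]] <- data.frame(
        tauD2 = gi("tauD2"), TD = gi("TD"), MA = gi("MA"),
        carbs = smp$meals$carbs[m], fat = smp$meals$fat[m],
        protein = smp$meals$protein[m], dCGM = y_cgm - 40)
    }
  }
  d <- do.call(rbind, rows)
  if (is.null(d) || nrow(d) < 10)
    stop("post-hoc meal regression needs at least 10 meals")
  fit1 <- function(resp) {
    f <- lm(stats::reformulate(c("carbs", "fat", "protein", "dCGM"), resp), data = d)
    ci <- stats::confint(f)
    sm <- summary(f)$coefficients
    data.frame(variable = rownames(sm), coef = sm[, 1], p = sm[, 4],
               ci_lo = ci[, 1], ci_hi = ci[, 2], row.names = NULL)
  }
  structure(list(tauD2 = fit1("tauD2"), TD = fit1("TD"), MA = fit1("MA"),
                 data = d), class = "meal_ols")
}

#' @export
print.meal_ols <- function(x, ...) {
  for (nm in c("tauD2", "TD", "MA")) {
    cat("==", nm, "==\n")
    print(x[[nm]], digits = 3)
  }
  invisible(x)
}
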