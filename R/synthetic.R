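# Synthetic virtual cohort with known ground truth: the no-download test
# bed for the pipeline, the hierarchy and the inference machinery.

#' Synthetic cohort configuration
#'
#' Defaults emulate the composition of a free-living MDI cohort: ~2.7
#' meals, ~1.9 paired fast-acting boluses and ~0.33 activities per 24h
#' window, bolus sizing at 1 U per 10 g carbohydrate with 20% noise,
#' resting heart rate 60-75 bpm with 40-80 bpm elevations during
#' exercise, and CGM noise drawn from the model's own prior but clamped
#' to a 4-9 mg/dL band. Noise is independent between readings by default,
#' matching the fitted likelihood; `noise_phi` optionally adds AR(1)
#' autocorrelation (as real sensor error has) for robustness studies --
#' note that fitting the independent-noise model to autocorrelated data
#' biases the smooth latents, which is the point of that mode.
#'
#' @param n_patients,samples_per_patient cohort size (windows are
#'   back-to-back days).
#' @param meal_counts,meal_count_probs distribution of meals/day.
#' @param carbs_meanlog,carbs_sdlog,carbs_range log-normal carbohydrate
#'   distribution (g), truncated to `carbs_range`.
#' @param bolus_prob_other probability that a non-first meal gets a bolus
#'   (the first always does, so windows have >= 1 injection).
#' @param bolus_per_10g,bolus_noise bolus sizing rule.
#' @param exercise_prob,exercise_dur,exercise_hr daily activity
#'   probability, duration range (min) and heart-rate elevation (bpm).
#' @param hr_base_range resting heart-rate range across patients (bpm).
#' @param hr_coverage fraction of 5-min bins with a heart-rate reading.
#' @param sigma_range CGM noise band (mg/dL); the default upper end keeps
#'   clean windows clear of the 45 mg/dL discontinuity filter.
#' @param noise_phi lag-1 autocorrelation of CGM noise (0 = independent).
#' @param basal_range daily long-acting dose range (U).
#' @param base_date calendar date of the first window.
#' @param max_retries regeneration attempts per window (see
#'   [generate_cohort()]).
#' @param seed RNG seed.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 10, samples_per_patient = 50,
                          meal_counts = c(2, 3, 4),
                          meal_count_probs = c(0.4, 0.5, 0.1),
                          carbs_meanlog = log(45), carbs_sdlog = 0.4,
                          carbs_range = c(10, 150),
                          bolus_prob_other = 0.505,
                          bolus_per_10g = 1, bolus_noise = 0.2,
                          exercise_prob = 0.33, exercise_dur = c(20, 60),
                          exercise_hr = c(40, 80),
                          hr_base_range = c(60, 75), hr_coverage = 0.8,
                          sigma_range = c(4, 9), noise_phi = 0,
                          basal_range = c(18, 30),
                          base_date = "2024-03-01", max_retries = 30,
                          seed = 1) {
  stopifnot(n_patients >= 1, samples_per_patient >= 1,
            all(meal_count_probs >= 0), exercise_prob >= 0, exercise_prob <= 1,
            hr_coverage >= 0, hr_coverage <= 1)
  structure(as.list(environment()), class = "cohort_config")
}

# one day's event schedule (times in minutes from that day's midnight)
.schedule_day <- function(cfg) {
  nm <- sample(cfg$meal_counts, 1, prob = cfg$meal_count_probs)
  wins <- list(c(420, 540), c(720, 840), c(1080, 1260), c(900, 1020))
  use <- if (nm <= 3) sort(sample(1:3, nm)) else 1:4
  mt <- sort(vapply(wins[use], function(w) runif(1, w[1], w[2]), 0))
  carbs <- pmin(pmax(exp(rnorm(nm, cfg$carbs_meanlog, cfg$carbs_sdlog)),
                     cfg$carbs_range[1]), cfg$carbs_range[2])
  carbs <- round(carbs)
  fat <- round(pmax(carbs * 0.4 + rnorm(nm, 0, 8), 0))
  protein <- round(pmax(carbs * 0.5 + rnorm(nm, 0, 10), 0))
  bol <- c(TRUE, runif(nm - 1) < cfg$bolus_prob_other)[seq_len(nm)]
  bt <- mt[bol] + runif(sum(bol), 0, 15)
  bd <- pmax(round(carbs[bol] / 10 * cfg$bolus_per_10g *
                     (1 + rnorm(sum(bol), 0, cfg$bolus_noise)), 1), 0.5)
  ex <- NULL
  if (runif(1) < cfg$exercise_prob) {
    ex <- data.frame(t = runif(1, 480, 1200),
                     dur = runif(1, cfg$exercise_dur[1], cfg$exercise_dur[2]),
                     dhr = runif(1, cfg$exercise_hr[1], cfg$exercise_hr[2]))
  }
  list(meals = data.frame(t = mt, carbs = carbs, fat = fat, protein = protein),
       boluses = data.frame(t = bt, dose = bd),
       exercise = if (is.null(ex)) data.frame(t = numeric(0), dur = numeric(0),
                                              dhr = numeric(0)) else ex)
}

.hr_day <- function(cfg, base, sched) {
  t <- seq(0, 1435, by = 5)
  bpm <- base + rnorm(length(t), 0, 3)
  if (nrow(sched$exercise) > 0) {
    for (e in seq_len(nrow(sched$exercise))) {
      on <- t >= sched$exercise$t[e] & t <= sched$exercise$t[e] + sched$exercise$dur[e]
      bpm[on] <- bpm[on] + sched$exercise$dhr[e]
    }
  }
  keep <- runif(length(t)) < cfg$hr_coverage
  keep[1] <- TRUE
  data.frame(t = t[keep], bpm = round(bpm[keep]))
}

# redraw one window's sample- and event-level latents given its parents
redraw_sample_latents <- function(z, nodes, s) {
  tab <- nodes$table
  rows <- which(!is.na(tab$sample) & tab$sample == s)
  for (i in rows) {
    loc <- switch(tab$loc_mode[i],
                  const = tab$loc_const[i],
                  parent = if (tab$family[i] == "lnorm") log(z[tab$loc_a[i]])
                           else z[tab$loc_a[i]],
                  egp = z[tab$loc_a[i]] + z[tab$loc_b[i]] * z[tab$loc_c[i]])
    sc <- if (tab$scale_mode[i] == "node") z[tab$scale_id[i]]
          else tab$scale_const[i]
    z[i] <- switch(tab$family[i],
      tnorm = rtnorm(1, loc, sc, tab$lower[i], tab$upper[i]),
      norm = rnorm(1, loc, sc),
      lnorm = exp(rnorm(1, loc, sc)),
      unif = runif(1, tab$lower[i], tab$upper[i]),
      expo = rexp(1, rate = 1 / loc),
      halfnorm = abs(rnorm(1, 0, sc)))
  }
  z
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws a full latent vector from the hierarchical prior, builds realistic
#' daily schedules (meals in breakfast / lunch / dinner windows with
#' jitter, boluses 0-15 min after their meals, occasional exercise with
#' heart-rate elevation), simulates every 24h window with the
#' analytic-forcing backend and overlays Normal(0, sigma_window) CGM noise
#' at 5-min cadence (optionally AR(1)-correlated, see [cohort_config()]).
#' Windows whose (noisy or noiseless) glucose leaves (20, 600) mg/dL or
#' whose CGM would fail the quality filters are regenerated with fresh
#' event jitter and fresh window-level latents (bounded retries), so every
#' clean window is pass-by-construction. Fully reproducible given
#' `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param dir optional output directory; when given, writes `cgm.csv`,
#'   `events.csv`, `hr.csv`, `truth.json` and `manifest.json`.
#' @return list with `records` (a `raw_records`), `samples` (model-ready
#'   [sample24h()]s, patient-major), `truth` (latent vector, node table,
#'   per-window engine slots), `nodes`, and `manifest`.
#' @export
generate_cohort <- function(config = cohort_config(), dir = NULL) {
  cfg <- config
  set.seed(cfg$seed)
  nP <- cfg$n_patients; nS <- cfg$samples_per_patient
  base <- as.POSIXct(paste0(cfg$base_date, " 00:00:00"), tz = "UTC")
  # schedules first (they fix the hierarchy's event counts)
  sched <- vector("list", nP * nS)
  hr_base <- runif(nP, cfg$hr_base_range[1], cfg$hr_base_range[2])
  basal_dose <- round(runif(nP, cfg$basal_range[1], cfg$basal_range[2]))
  for (p in seq_len(nP)) for (d in seq_len(nS))
    sched[[(p - 1) * nS + d]] <- .schedule_day(cfg)
  hier <- vp_hierarchy(nP, nS,
                       vapply(sched, function(s) nrow(s$meals), 0L),
                       vapply(sched, function(s) nrow(s$boluses), 0L),
                       vapply(sched, function(s) nrow(s$exercise), 0L))
  nodes <- build_nodes(hier)
  z <- sample_latents(nodes, 1)$z[, 1]
  # clamp the generator's CGM noise to the device band
  isig <- nodes$table$latent == "sigma" & nodes$table$level == "sample"
  z[isig] <- pmin(pmax(z[isig], cfg$sigma_range[1]), cfg$sigma_range[2])

  samples <- vector("list", nP * nS)
  cgm_rows <- list(); ev_rows <- list(); hr_rows <- list()
  G_prev <- rep(NA_real_, nP)
  n_retries <- integer(nP * nS)
  for (p in seq_len(nP)) {
    # one long-acting injection per day at 22:00, starting the evening
    # before the first window
    for (d in 0:(nS)) {
      ev_rows[[length(ev_rows) + 1]] <- data.frame(
        patient_id = sprintf("P%02d", p),
        timestamp = base + ((d - 1) * 1440 + 1320) * 60,
        type = "basal", value = basal_dose[p], fat_g = NA, protein_g = NA)
    }
    for (d in seq_len(nS)) {
      s <- (p - 1) * nS + d
      day0 <- base + (d - 1) * 86400
      G0 <- if (is.na(G_prev[p])) runif(1, 120, 180) else G_prev[p]
      ok <- FALSE
      for (try in seq_len(cfg$max_retries)) {
        sc <- sched[[s]]
        hr <- .hr_day(cfg, hr_base[p], sc)
        rest <- as.numeric(quantile(hr$bpm, 0.05))
        smp <- sample24h(
          cgm = data.frame(t = c(0, 1435), glucose = c(G0, G0)), # placeholder
          meals = sc$meals[, c("t", "carbs", "fat", "protein")],
          boluses = sc$boluses, exercise = sc$exercise[, "t", drop = FALSE],
          hr = hr, basal = basal_dose[p] / 1440, hr_rest = rest,
          start_min = 0, patient_id = sprintf("P%02d", p),
          window_start = day0)
        smp$G0 <- G0
        ed <- as_engine_data(smp)
        out <- cpp_simulate(z[nodes$slot_map[[s]]], ed, 5, "analytic_forcing", 0.25)
        tcgm <- seq(0, 1435, by = 5)
        if (out$ok) {
          sg <- out$SG[1 + tcgm / 5]
          sig <- z[nodes$slot_map[[s]][16]]
          e <- if (cfg$noise_phi == 0) rnorm(length(tcgm), 0, sig) else
            as.numeric(stats::filter(rnorm(length(tcgm), 0,
                                           sig * sqrt(1 - cfg$noise_phi^2)),
                                     cfg$noise_phi, method = "recursive",
                                     init = rnorm(1, 0, sig)))
          cgm <- sg + e
          okg <- all(out$G > 20 & out$G < 600) && all(cgm > 20 & cgm < 600) &&
            max(abs(diff(cgm))) < 45
          if (okg) {
            smp$cgm <- data.frame(t = tcgm, glucose = cgm)
            smp$G0 <- cgm[1]
            # keep the window-initial CGM consistent with the model's
            # convention (initial glucose = first reading): regenerate the
            # trace from the noisy initial value
            ed2 <- as_engine_data(smp)
            out2 <- cpp_simulate(z[nodes$slot_map[[s]]], ed2, 5,
                                 "analytic_forcing", 0.25)
            if (out2$ok && all(out2$G > 20 & out2$G < 600)) {
              cgm2 <- out2$SG[1 + tcgm / 5] + e
              cgm2[1] <- smp$G0
              if (all(cgm2 > 20 & cgm2 < 600) && max(abs(diff(cgm2))) < 45) {
                smp$cgm$glucose <- cgm2
                G_prev[p] <- out2$G[length(out2$G)]
                samples[[s]] <- smp
                ok <- TRUE
              }
            }
          }
        }
        if (ok) break
        # fresh jitter and fresh window-level latents
        sched[[s]] <- .schedule_day_same_counts(cfg, sched[[s]])
        z <- redraw_sample_latents(z, nodes, s)
        z[nodes$slot_map[[s]][16]] <- min(max(z[nodes$slot_map[[s]][16]],
                                              cfg$sigma_range[1]),
                                          cfg$sigma_range[2])
        n_retries[s] <- n_retries[s] + 1L
      }
      if (!ok) stop(sprintf("window %d: no valid realization after %d retries",
                            s, cfg$max_retries))
      smp <- samples[[s]]
      cgm_rows[[s]] <- data.frame(patient_id = smp$patient_id,
                                  timestamp = day0 + smp$cgm$t * 60,
                                  glucose = smp$cgm$glucose)
      hr_rows[[s]] <- data.frame(patient_id = smp$patient_id,
                                 timestamp = day0 + smp$hr$t * 60,
                                 bpm = smp$hr$bpm)
      sc <- sched[[s]]
      ev <- rbind(
        if (nrow(sc$meals)) data.frame(patient_id = smp$patient_id,
                                       timestamp = day0 + sc$meals$t * 60,
                                       type = "meal", value = sc$meals$carbs,
                                       fat_g = sc$meals$fat,
                                       protein_g = sc$meals$protein),
        if (nrow(sc$boluses)) data.frame(patient_id = smp$patient_id,
                                         timestamp = day0 + sc$boluses$t * 60,
                                         type = "bolus", value = sc$boluses$dose,
                                         fat_g = NA, protein_g = NA),
        if (nrow(sc$exercise)) data.frame(patient_id = smp$patient_id,
                                          timestamp = day0 + sc$exercise$t * 60,
                                          type = "exercise", value = sc$exercise$dur,
                                          fat_g = NA, protein_g = NA))
      if (!is.null(ev)) ev_rows[[length(ev_rows) + 1]] <- ev
    }
  }
  cgm_all <- do.call(rbind, cgm_rows)
  ev_all <- do.call(rbind, ev_rows)
  ev_all <- ev_all[order(ev_all$patient_id, ev_all$timestamp), ]
  hr_all <- do.call(rbind, hr_rows)
  records <- .records_from_frames(cgm_all, ev_all, hr_all)
  truth <- list(z = setNames(z, nodes$table$name),
                slots = lapply(seq_along(samples),
                               function(s) setNames(z[nodes$slot_map[[s]]],
                                                    slot_names(nodes, s))),
                hr_base = hr_base, basal_dose = basal_dose)
  manifest <- list(config = unclass(cfg)[setdiff(names(cfg), "")],
                   n_windows = nP * nS, window_stride_min = 1440,
                   designed_pass = nP * nS, retries = n_retries)
  out <- list(records = records, samples = samples, truth = truth,
              nodes = nodes, manifest = manifest)
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

# fresh jitter with the same event counts (keeps the hierarchy layout)
.schedule_day_same_counts <- function(cfg, old) {
  repeat {
    s <- .schedule_day(cfg)
    if (nrow(s$meals) == nrow(old$meals) &&
        nrow(s$boluses) == nrow(old$boluses) &&
        nrow(s$exercise) == nrow(old$exercise)) return(s)
  }
}

slot_names <- function(nodes, s) nodes$table$name[nodes$slot_map[[s]]]

.records_from_frames <- function(cgm, ev, hr) {
  ids <- unique(cgm$patient_id)
  out <- lapply(ids, function(id) {
    list(cgm = cgm[cgm$patient_id == id, c("timestamp", "glucose")],
         events = ev[ev$patient_id == id,
                     c("timestamp", "type", "value", "fat_g", "protein_g")],
         hr = hr[hr$patient_id == id, c("timestamp", "bpm")])
  })
  names(out) <- ids
  for (id in ids) for (nm in names(out[[id]])) rownames(out[[id]][[nm]]) <- NULL
  structure(out, class = "raw_records")
}

#' Write a generated cohort to plain-text files
#'
#' `cgm.csv`, `events.csv`, `hr.csv` (the raw-record schemas of
#' [read_records()]), `truth.json` (ground-truth latents and per-window
#' slots) and `manifest.json`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(d) {
    d$timestamp <- format(d$timestamp, "%Y-%m-%dT%H:%M:%S")
    d
  }
  allof <- function(field) do.call(rbind, lapply(names(cohort$records), function(id)
    cbind(patient_id = id, cohort$records[[id]][[field]])))
  write.csv(fmt(allof("cgm")), file.path(dir, "cgm.csv"), row.names = FALSE)
  write.csv(fmt(allof("events")), file.path(dir, "events.csv"), row.names = FALSE)
  write.csv(fmt(allof("hr")), file.path(dir, "hr.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Inject data-quality defects into raw records
#'
#' Deterministically damages chosen windows so that specific quality
#' filters fail: `"gap"` removes CGM readings to open a >12 min hole,
#' `"jump"` offsets the second half of the window by +60 mg/dL,
#' `"no_meals"`, `"no_bolus"` and `"no_hr"` delete the corresponding
#' records. Returns the damaged records plus a manifest of the expected
#' filter outcome per damaged window.
#'
#' @param records a `raw_records`.
#' @param defect_spec data.frame with `patient_id`, `window` (1-based day
#'   index from each patient's first CGM reading) and `type`.
#' @return list with `records` and `manifest` (expected failing rule per
#'   defect).
#' @export
inject_defects <- function(records, defect_spec) {
  stopifnot(all(c("patient_id", "window", "type") %in% names(defect_spec)))
  man <- defect_spec
  man$fails_rule <- NA_integer_
  for (i in seq_len(nrow(defect_spec))) {
    id <- as.character(defect_spec$patient_id[i])
    if (!id %in% names(records)) stop("unknown patient in defect spec")
    r <- records[[id]]
    t0 <- r$cgm$timestamp[1] + (defect_spec$window[i] - 1) * 86400
    t1 <- t0 + 86400
    if (t0 > r$cgm$timestamp[nrow(r$cgm)]) stop("defect outside data span")
    inw <- function(ts) ts >= t0 & ts < t1
    type <- as.character(defect_spec$type[i])
    if (type == "gap") {
      drop <- inw(r$cgm$timestamp) &
        r$cgm$timestamp >= t0 + 600 * 60 & r$cgm$timestamp <= t0 + 610 * 60
      r$cgm <- r$cgm[!drop, ]
      man$fails_rule[i] <- 1L
    } else if (type == "jump") {
      # dip one interior reading 60 mg/dL below its neighbours, so at
      # least one consecutive discontinuity is >= 45 by construction
      idx <- which(inw(r$cgm$timestamp))
      idx <- idx[idx > min(idx) & idx < max(idx)]
      nb <- pmin(r$cgm$glucose[idx - 1], r$cgm$glucose[idx + 1])
      k <- idx[which.max(nb)]
      r$cgm$glucose[k] <- max(nb) - 60
      man$fails_rule[i] <- 2L
    } else if (type == "no_meals") {
      k <- r$events$type == "meal" & inw(r$events$timestamp)
      r$events <- r$events[!k, ]
      man$fails_rule[i] <- 3L
    } else if (type == "no_bolus") {
      k <- r$events$type == "bolus" & inw(r$events$timestamp)
      r$events <- r$events[!k, ]
      man$fails_rule[i] <- 4L
    } else if (type == "no_hr") {
      k <- inw(r$hr$timestamp)
      r$hr <- r$hr[!k, ]
      man$fails_rule[i] <- 5L
    } else stop("unknown defect type: ", type)
    records[[id]] <- r
  }
  list(records = records, manifest = man)
}
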