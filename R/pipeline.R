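# Ingestion of raw CGM / event / heart-rate streams and preparation of
# filtered 24h sample windows.

.parse_ts <- function(x) {
  t <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
  na <- is.na(t)
  if (any(na)) t[na] <- as.POSIXct(x[na], tz = "UTC")
  t
}

#' Read raw patient records from CSV streams
#'
#' Expected schemas: `cgm.csv` with `patient_id, timestamp, glucose`
#' (mg/dL); `events.csv` with `patient_id, timestamp, type, value, fat_g,
#' protein_g` where `type` is one of `meal` (value = carbohydrate grams),
#' `bolus` (fast-acting insulin units), `basal` (long-acting units) or
#' `exercise`; `hr.csv` with `patient_id, timestamp, bpm`. Timestamps are
#' timezone-naive ISO 8601. Glucose readings outside the (20, 600) mg/dL
#' plausibility band are dropped with a warning.
#'
#' @param cgm_file,events_file,hr_file CSV paths.
#' @return `raw_records`: named list (one entry per patient) of
#'   `list(cgm, events, hr)` data.frames with POSIXct `timestamp`s.
#' @export
read_records <- function(cgm_file, events_file, hr_file) {
  cgm <- read.csv(cgm_file, colClasses = c(patient_id = "character"))
  ev <- read.csv(events_file, colClasses = c(patient_id = "character"))
  hr <- read.csv(hr_file, colClasses = c(patient_id = "character"))
  cgm$timestamp <- .parse_ts(cgm$timestamp)
  ev$timestamp <- .parse_ts(ev$timestamp)
  hr$timestamp <- .parse_ts(hr$timestamp)
  bad <- cgm$glucose <= 20 | cgm$glucose >= 600
  if (any(bad)) {
    warning(sprintf("%d CGM reading(s) outside (20, 600) mg/dL dropped", sum(bad)))
    cgm <- cgm[!bad, ]
  }
  ids <- unique(cgm$patient_id)
  out <- lapply(ids, function(id) {
    r <- list(cgm = cgm[cgm$patient_id == id, c("timestamp", "glucose")],
              events = ev[ev$patient_id == id,
                          c("timestamp", "type", "value", "fat_g", "protein_g")],
              hr = hr[hr$patient_id == id, c("timestamp", "bpm")])
    for (nm in names(r)) {
      r[[nm]] <- r[[nm]][order(r[[nm]]$timestamp), ]
      rownames(r[[nm]]) <- NULL
    }
    if (is.unsorted(as.numeric(r$cgm$timestamp), strictly = TRUE))
      stop(sprintf("duplicate CGM timestamps for patient %s", id))
    r
  })
  names(out) <- ids
  structure(out, class = "raw_records")
}

#' Candidate 24h windows over a patient's CGM span
#'
#' Greedy left-to-right placement: the first window starts at the first
#' CGM reading and each subsequent start is `min_stride` after the
#' previous one, as long as the full window fits inside the data span.
#' A span shorter than the window yields no candidates (not an error).
#'
#' @param records one patient's entry of [read_records()] (or any list
#'   with a `cgm` data.frame).
#' @param length_min window length (min).
#' @param min_stride minimal spacing of window starts (min).
#' @return POSIXct vector of window starts.
#' @export
extract_windows <- function(records, length_min = 1440, min_stride = 300) {
  cgm <- records$cgm
  if (nrow(cgm) == 0) return(.parse_ts(character(0)))
  t0 <- cgm$timestamp[1]
  span <- as.numeric(difftime(cgm$timestamp[nrow(cgm)], t0, units = "mins"))
  # the last reading covers one nominal cadence of data
  if (nrow(cgm) > 2) span <- span + median(diff(as.numeric(cgm$timestamp))) / 60
  if (span < length_min) return(t0[0])
  starts <- seq(0, span - length_min, by = min_stride)
  t0 + starts * 60
}

#' Materialize one 24h window from raw records
#'
#' Cuts all streams to window-relative minutes. The window is half-open,
#' `[start, start + 1440)`: events exactly at the right edge are excluded.
#' Long-acting (`basal`) injections from the preceding 24 h are kept
#' separately for [prepare_sample()].
#'
#' @param records one patient's raw records.
#' @param start window start (POSIXct).
#' @param length_min window length.
#' @return a `window24h` list.
#' @export
materialize_window <- function(records, start, length_min = 1440) {
  rel <- function(ts) as.numeric(difftime(ts, start, units = "mins"))
  inw <- function(t) t >= 0 & t < length_min
  cgm <- records$cgm; ev <- records$events; hr <- records$hr
  tc <- rel(cgm$timestamp)
  th <- rel(hr$timestamp)
  te <- rel(ev$timestamp)
  meals <- ev[ev$type == "meal" & inw(te), ]
  bol <- ev[ev$type == "bolus" & inw(te), ]
  exr <- ev[ev$type == "exercise" & inw(te), ]
  basal_prev <- ev[ev$type == "basal" & te >= -1440 & te <= 0, ]
  lt <- as.POSIXlt(start)
  structure(list(
    start = start,
    start_min = lt$hour * 60 + lt$min + lt$sec / 60,
    length_min = length_min,
    cgm = data.frame(t = tc[inw(tc)], glucose = cgm$glucose[inw(tc)]),
    hr = data.frame(t = th[inw(th)], bpm = hr$bpm[inw(th)]),
    meals = data.frame(t = rel(meals$timestamp), carbs = meals$value,
                       fat = ifelse(is.na(meals$fat_g), 0, meals$fat_g),
                       protein = ifelse(is.na(meals$protein_g), 0, meals$protein_g)),
    boluses = data.frame(t = rel(bol$timestamp), dose = bol$value),
    exercise = data.frame(t = rel(exr$timestamp)),
    basal_prev = data.frame(t = rel(basal_prev$timestamp), dose = basal_prev$value)),
    class = "window24h")
}

#' The five sample-quality filters
#'
#' A window passes when all five rules hold: (1) no gap between
#' consecutive CGM readings exceeding 12 min; (2) no discontinuity of
#' 45 mg/dL or more between consecutive readings; (3) at least 2 meals;
#' (4) at least 1 fast-acting bolus; (5) heart-rate readings in at least
#' 30% of the window's 5-min bins. The rules are checked independently
#' (order-free) and the report carries the offending values.
#'
#' @param window a [materialize_window()] result.
#' @param id optional window identifier for the report.
#' @return one-row data.frame (`filter_report`).
#' @export
apply_filters <- function(window, id = NA) {
  cgm <- window$cgm
  gaps <- diff(cgm$t)
  jumps <- abs(diff(cgm$glucose))
  max_gap <- if (length(gaps)) max(gaps) else Inf
  max_jump <- if (length(jumps)) max(jumps) else 0
  nbins <- ceiling(window$length_min / 5)
  cov <- length(unique(pmin(floor(window$hr$t / 5), nbins - 1))) / nbins
  r <- data.frame(
    id = id,
    rule1_gap = max_gap <= 12,
    rule2_jump = max_jump < 45,
    rule3_meals = nrow(window$meals) >= 2,
    rule4_bolus = nrow(window$boluses) >= 1,
    rule5_hr = cov >= 0.30,
    max_gap = max_gap, max_jump = max_jump,
    n_meals = nrow(window$meals), n_boluses = nrow(window$boluses),
    hr_coverage = cov)
  r$pass <- r$rule1_gap & r$rule2_jump & r$rule3_meals & r$rule4_bolus & r$rule5_hr
  r
}

#' Prepare a filtered window as a model-ready sample
#'
#' Converts the most recent long-acting injection of the preceding 24 h
#' into a constant basal rate `dose / 1440` U/min active for the whole
#' window (warning and zero basal when there is none), sets the initial
#' glucose to the first CGM reading, and re-times all events to
#' window-relative minutes.
#'
#' @param window a [materialize_window()] result (that passed
#'   [apply_filters()]).
#' @param patient_id,hr_rest passed to [sample24h()].
#' @return a [sample24h()].
#' @export
prepare_sample <- function(window, patient_id = NA_character_,
                           hr_rest = NULL) {
  basal <- 0
  if (nrow(window$basal_prev) > 0) {
    basal <- window$basal_prev$dose[which.max(window$basal_prev$t)] / 1440
  } else {
    warning("no long-acting injection in the preceding 24 h; basal set to 0")
  }
  sample24h(cgm = window$cgm, meals = window$meals, boluses = window$boluses,
            exercise = window$exercise, hr = window$hr, basal = basal,
            hr_rest = hr_rest, start_min = window$start_min,
            patient_id = patient_id, window_start = window$start)
}

#' Run the whole extraction pipeline over raw records
#'
#' Extracts candidate windows per patient, applies the five filters, and
#' prepares every passing window.
#'
#' @param records a [read_records()] result.
#' @param min_stride minimal window-start spacing (min).
#' @param hr_rest_q quantile of each patient's heart-rate readings used as
#'   their resting rate.
#' @return list with `samples` (passing [sample24h()]s, patient-major) and
#'   `report` (all windows' filter reports, with `patient_id`).
#' @export
process_records <- function(records, min_stride = 300, hr_rest_q = 0.05) {
  samples <- list(); reports <- list()
  for (id in names(records)) {
    r <- records[[id]]
    hr_rest <- if (nrow(r$hr) > 0) as.numeric(quantile(r$hr$bpm, hr_rest_q)) else 60
    starts <- extract_windows(r, min_stride = min_stride)
    for (k in seq_along(starts)) {
      w <- materialize_window(r, starts[k])
      rep_k <- apply_filters(w, id = sprintf("%s_w%d", id, k))
      rep_k$patient_id <- id
      reports[[length(reports) + 1]] <- rep_k
      if (rep_k$pass) {
        samples[[length(samples) + 1]] <-
          suppressWarnings(prepare_sample(w, patient_id = id, hr_rest = hr_rest))
      }
    }
  }
  list(samples = samples,
       report = if (length(reports)) do.call(rbind, reports) else NULL)
}
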