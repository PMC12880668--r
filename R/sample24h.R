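#' Construct a 24-hour sample window
#'
#' A `sample24h` bundles everything the simulator and likelihood need for
#' one 24h window: the CGM trace on window-relative minutes, heart rate,
#' the in-window events, the constant basal rate derived from the most
#' recent long-acting injection, and the initial glucose (first CGM
#' reading, which seeds both the blood and subcutaneous compartments).
#'
#' @param cgm data.frame with `t` (min in `[0, 1440)`) and `glucose` (mg/dL).
#' @param meals data.frame with `t`, `carbs` and optionally `fat`, `protein`
#'   (g).
#' @param boluses data.frame with `t` and `dose` (U).
#' @param exercise data.frame with `t`.
#' @param hr data.frame with `t` and `bpm` (possibly sparse).
#' @param basal constant basal rate (U/min), from dose / 1440.
#' @param hr_rest resting heart rate (bpm); default the 5th percentile of
#'   the window's readings (falls back to 60 bpm when there are none).
#' @param start_min clock time of the window start in minutes after local
#'   midnight (anchors the intraday sinusoid).
#' @param patient_id,window_start optional identifiers.
#' @return object of class `sample24h`.
#' @export
sample24h <- function(cgm, meals = NULL, boluses = NULL, exercise = NULL,
                      hr = NULL, basal = 0, hr_rest = NULL, start_min = 0,
                      patient_id = NA_character_, window_start = NA) {
  stopifnot(is.data.frame(cgm), all(c("t", "glucose") %in% names(cgm)),
            nrow(cgm) >= 2)
  if (is.unsorted(cgm$t, strictly = TRUE)) stop("CGM timestamps must be strictly increasing")
  empty <- function(cols) as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  if (is.null(meals)) meals <- empty(c("t", "carbs", "fat", "protein"))
  if (is.null(boluses)) boluses <- empty(c("t", "dose"))
  if (is.null(exercise)) exercise <- empty("t")
  if (is.null(hr)) hr <- empty(c("t", "bpm"))
  if (!"fat" %in% names(meals)) meals$fat <- 0
  if (!"protein" %in% names(meals)) meals$protein <- 0
  if (is.null(hr_rest)) {
    hr_rest <- if (nrow(hr) > 0) as.numeric(quantile(hr$bpm, 0.05)) else 60
  }
  if (basal < 0) stop("basal rate must be non-negative")
  structure(list(cgm = cgm, meals = meals, boluses = boluses,
                 exercise = exercise, hr = hr, basal = basal,
                 hr_rest = hr_rest, start_min = start_min, t_end = 1440,
                 G0 = cgm$glucose[1], patient_id = patient_id,
                 window_start = window_start),
            class = "sample24h")
}

#' @export
print.sample24h <- function(x, ...) {
  cat(sprintf("<sample24h> patient %s, start %s\n", x$patient_id,
              format(x$window_start)))
  cat(sprintf("  CGM: %d readings, G0 = %.0f mg/dL; HR: %d readings (rest %.0f bpm)\n",
              nrow(x$cgm), x$G0, nrow(x$hr), x$hr_rest))
  cat(sprintf("  events: %d meals, %d boluses, %d activities; basal %.3f U/min\n",
              nrow(x$meals), nrow(x$boluses), nrow(x$exercise), x$basal))
  invisible(x)
}

# Engine-facing representation (list consumed by the C++ likelihood).
as_engine_data <- function(s, hold_max = 15) {
  stopifnot(inherits(s, "sample24h"))
  pw <- hr_to_pwc(s$hr$t, s$hr$bpm, s$hr_rest, hold_max)
  list(cgm_t = as.numeric(s$cgm$t), cgm_y = as.numeric(s$cgm$glucose),
       meal_t = as.numeric(s$meals$t), meal_carbs = as.numeric(s$meals$carbs),
       bol_t = as.numeric(s$boluses$t), bol_dose = as.numeric(s$boluses$dose),
       ex_t = as.numeric(s$exercise$t),
       hr_bt = pw$t, hr_bu = pw$u,
       basal = as.numeric(s$basal), start_min = as.numeric(s$start_min),
       t_end = as.numeric(s$t_end), G0 = as.numeric(s$G0),
       SG0 = as.numeric(s$G0))
}

#' Write / read a sample window as a set of CSV files
#'
#' Plain-text round trip: `<stem>_cgm.csv`, `<stem>_events.csv`,
#' `<stem>_hr.csv` and `<stem>_meta.csv`. Traces round-trip bit-exactly
#' (values are written with full precision).
#'
#' @param s a `sample24h`.
#' @param stem file path stem.
#' @return `read_sample24h` returns a `sample24h`.
#' @export
write_sample24h <- function(s, stem) {
  wr <- function(d, f) write.csv(format(d, digits = 17, trim = TRUE,
                                        scientific = FALSE),
                                 f, row.names = FALSE, quote = FALSE)
  wr(s$cgm, paste0(stem, "_cgm.csv"))
  blk <- function(type, t, value, fat, protein) {
    if (length(t) == 0)
      return(data.frame(type = character(0), t = numeric(0),
                        value = numeric(0), fat_g = numeric(0),
                        protein_g = numeric(0)))
    data.frame(type = type, t = t, value = value, fat_g = fat,
               protein_g = protein)
  }
  ev <- rbind(
    blk("meal", s$meals$t, s$meals$carbs, s$meals$fat, s$meals$protein),
    blk("bolus", s$boluses$t, s$boluses$dose, NA, NA),
    blk("exercise", s$exercise$t, NA, NA, NA))
  wr(ev, paste0(stem, "_events.csv"))
  wr(s$hr, paste0(stem, "_hr.csv"))
  wr(data.frame(patient_id = s$patient_id,
                window_start = as.character(s$window_start),
                basal = s$basal, hr_rest = s$hr_rest,
                start_min = s$start_min), paste0(stem, "_meta.csv"))
  invisible(stem)
}

#' @rdname write_sample24h
#' @export
read_sample24h <- function(stem) {
  cgm <- read.csv(paste0(stem, "_cgm.csv"))
  ev <- read.csv(paste0(stem, "_events.csv"))
  hr <- read.csv(paste0(stem, "_hr.csv"))
  meta <- read.csv(paste0(stem, "_meta.csv"), colClasses = c(patient_id = "character"))
  m <- ev[ev$type == "meal", ]
  b <- ev[ev$type == "bolus", ]
  x <- ev[ev$type == "exercise", ]
  sample24h(cgm,
            meals = data.frame(t = m$t, carbs = m$value, fat = m$fat_g,
                               protein = m$protein_g),
            boluses = data.frame(t = b$t, dose = b$value),
            exercise = data.frame(t = x$t),
            hr = hr, basal = meta$basal, hr_rest = meta$hr_rest,
            start_min = meta$start_min, patient_id = meta$patient_id,
            window_start = meta$window_start)
}
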