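# Independent oracles used by the chain tests: plain-R fixed-step RK4
# integration of the cascade ODEs, written without reference to the
# package's impulse-response machinery.

# Cascade of unit-DC-gain first-order stages y_i' = (u_{i-1} - y_i)/tau_i,
# driven by a constant level plus an optional impulse into stage 1 at t0
# (state jump mass/tau_1). Returns stage-k output sampled at t_out.
rk4_chain_oracle <- function(taus, t_out, dt = 0.01, impulse_t = NA,
                             impulse_mass = 0, step_level = 0, y0 = NULL,
                             gain_final = 1) {
  k <- length(taus)
  y <- if (is.null(y0)) numeric(k) else y0
  deriv <- function(y) {
    u <- c(step_level, y[-k])
    (u - y) / taus
  }
  t_end <- max(t_out)
  n <- round(t_end / dt)
  out <- numeric(length(t_out))
  oi <- 1L
  if (!is.na(impulse_t) && impulse_t <= 0) y[1] <- y[1] + impulse_mass / taus[1]
  for (i in seq_len(n + 1)) {
    t <- (i - 1) * dt
    while (oi <= length(t_out) && t_out[oi] <= t + 1e-6) {
      out[oi] <- y[k] * gain_final
      oi <- oi + 1L
    }
    if (i > n) break
    k1 <- deriv(y)
    k2 <- deriv(y + dt / 2 * k1)
    k3 <- deriv(y + dt / 2 * k2)
    k4 <- deriv(y + dt * k3)
    y <- y + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!is.na(impulse_t) && impulse_t > t + 1e-9 && impulse_t <= t + dt + 1e-9)
      y[1] <- y[1] + impulse_mass / taus[1]
  }
  out
}

# relative error against an oracle, normalized by the oracle's peak
rel_err <- function(x, ref) max(abs(x - ref)) / max(abs(ref))

# a compact, well-behaved synthetic day used across tests
demo_day <- function(seed = 42, n_meals = 3, exercise = TRUE) {
  set.seed(seed)
  tg <- seq(0, 1435, by = 5)
  meals <- data.frame(t = c(480, 760, 1140)[seq_len(n_meals)],
                      carbs = c(50, 70, 60)[seq_len(n_meals)],
                      fat = c(15, 25, 20)[seq_len(n_meals)],
                      protein = c(20, 30, 25)[seq_len(n_meals)])
  boluses <- data.frame(t = meals$t + 7, dose = round(meals$carbs / 10, 1))
  hr <- data.frame(t = tg, bpm = 65 + rnorm(length(tg), 0, 2))
  ex <- NULL
  if (exercise) {
    ex <- data.frame(t = 1000)
    on <- tg >= 1000 & tg <= 1040
    hr$bpm[on] <- hr$bpm[on] + 55
  }
  cgm <- data.frame(t = tg, glucose = 150 + 20 * sin(tg / 400))
  sample24h(cgm, meals = meals, boluses = boluses, exercise = ex, hr = hr,
            basal = 24 / 1440, start_min = 0, patient_id = "demo",
            window_start = as.POSIXct("2024-03-01", tz = "UTC"))
}
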