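# Whole-window simulation: fixed points, qualitative behaviour, backend
# agreement and trace output.

test_that("zero-input fixed point G0 = EGP/GEZI holds over 24 h", {
  G0 <- 150
  p <- sim_params(EGP = 0.3, GEZI = 0.002, X0 = 0, S0 = 0, Ip0 = 0, SIA = 0,
                  SE = 0)
  s <- sample24h(cgm = data.frame(t = c(0, 1435), glucose = c(G0, G0)),
                 basal = 0)
  tr <- simulate_sample(p, s, dt = 1)
  expect_lt(max(abs(tr$G - G0)), 0.1)
  expect_lt(max(abs(tr$SG - G0)), 0.1)
})

test_that("without insulin and meals glucose rises to the renal ceiling", {
  p <- sim_params(EGP = 1.6, GEZI = 0.002, X0 = 0, S0 = 0, Ip0 = 0, SIA = 0,
                  SE = 0)
  s <- sample24h(cgm = data.frame(t = c(0, 1435), glucose = c(150, 150)),
                 basal = 0)
  tr <- simulate_sample(p, s, dt = 1)
  expect_true(all(diff(tr$G) > -1e-9))          # monotone rise
  expect_gt(tr$G[length(tr$G)], 300)            # near the ~400 mg/dL ceiling
  expect_true(all(tr$FR[tr$G <= 162] == 0))
})

test_that("analytic-forcing and full-ODE backends agree on a loaded day", {
  s <- demo_day()
  s$meals$TD <- c(12, 18, 8); s$meals$tauD2 <- c(35, 55, 45)
  s$meals$MA <- c(1.1, 0.9, 1.0)
  s$boluses$TI <- c(4, 6, 3); s$boluses$tauI1 <- c(14, 18, 16)
  s$boluses$IA <- c(1, 1.2, 0.9)
  s$exercise$TP <- 5; s$exercise$tauP_long <- 900
  s$exercise$tauP_short <- 60; s$exercise$P_long <- 0.5
  s$exercise$P_short <- -0.2
  p <- sim_params(SIA = 0.3, SIphi = 0.2, SE = 0.012, H = 0.4)
  a <- simulate_sample(p, s, dt = 1, backend = "analytic_forcing")
  b <- simulate_sample(p, s, dt = 1, backend = "full_ode", ode_dt = 0.05)
  expect_lt(max(abs(a$SG - b$SG)), 0.5)
  expect_lt(max(abs(a$G - b$G)), 0.5)
  expect_lt(rel_err(a$RA, b$RA), 1e-3)
  expect_lt(rel_err(a$X, b$X), 1e-3)
  # positivity of compartment outputs under valid inputs
  expect_true(all(a$RA >= 0) && all(a$X >= 0) && all(a$E >= -1e-12))
  expect_true(all(a$G > 0) && all(a$SG > 0) && all(a$FR >= 0))
})

test_that("negative report offsets (event onsets before the window) agree across backends", {
  s <- demo_day(exercise = FALSE, n_meals = 1)
  s$meals$t <- 10; s$meals$TD <- -25    # onset at -15 min
  s$boluses <- s$boluses[1, ]; s$boluses$t <- 5; s$boluses$TI <- -20
  p <- sim_params()
  a <- simulate_sample(p, s, dt = 1, backend = "analytic_forcing")
  b <- simulate_sample(p, s, dt = 1, backend = "full_ode", ode_dt = 0.05)
  expect_lt(max(abs(a$SG - b$SG)), 0.5)
  expect_gt(a$RA[1], 0)   # absorption already under way at t = 0
})

test_that("integration failure reports the offending time", {
  # a strong sustained metabolic drain with no production pushes glucose
  # through zero: the simulator must fail with the offending time, not NaN
  hr_t <- seq(0, 1435, by = 5)
  p <- sim_params(EGP = 0, GEZI = 1e-3, SE = 0.05, X0 = 0, S0 = 0, Ip0 = 0)
  s <- sample24h(cgm = data.frame(t = c(0, 1435), glucose = c(60, 60)),
                 hr = data.frame(t = hr_t, bpm = rep(160, length(hr_t))),
                 basal = 0, hr_rest = 60)
  expect_error(simulate_sample(p, s, dt = 1), "t = ")
})

test_that("trace bundles round-trip through CSV", {
  tr <- simulate_sample(sim_params(), demo_day(exercise = FALSE), dt = 5)
  f <- tempfile(fileext = ".csv")
  write_trace(tr, f)
  d <- read.csv(f)
  expect_identical(names(d)[1:3], c("t_min", "SG", "G"))
  expect_equal(d$SG, tr$SG, tolerance = 1e-6)
})
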