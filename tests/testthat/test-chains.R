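# Compartment-chain forcings: conservation, closed-form identities, and
# equivalence with brute-force ODE integration (including repeated poles).

test_that("meal chain conserves carbohydrate mass and handles zero input", {
  t <- seq(0, 4000, by = 0.5)
  expect_identical(meal_ra(t, carbs = 0, VG = 100, tauD1 = 10, tauD2 = 40),
                   numeric(length(t)))
  # VG * integral(RA) = bioavailability * MA * carbs * 1000
  for (ma in c(1, 1.3)) {
    ra <- meal_ra(t, carbs = 60, VG = 100, tauD1 = 10, tauD2 = 40, MA = ma)
    mass <- 100 * sum(ra) * 0.5
    expect_lt(abs(mass / (0.8 * ma * 60 * 1000) - 1), 1e-3)
  }
  # single 60 g meal with MA = 1 recovers the fixed 0.8 bioavailability
  ra <- meal_ra(t, carbs = 60, VG = 100, tauD1 = 10, tauD2 = 40)
  expect_equal(100 * sum(ra) * 0.5 / (60 * 1000), 0.8, tolerance = 1e-3)
  expect_error(meal_ra(t, carbs = 60, VG = 100, tauD1 = -1, tauD2 = 40),
               "positive")
  expect_error(meal_ra(t, carbs = -5, VG = 100, tauD1 = 10, tauD2 = 40),
               "non-negative")
})

test_that("meal chain matches brute-force RK4 of the compartment ODEs", {
  t_out <- 0:600
  ra <- meal_ra(t_out, carbs = 60, VG = 100, tauD1 = 10, tauD2 = 40)
  mass <- 0.8 * 60 * 1000 / 100
  ref <- rk4_chain_oracle(c(10, 40, 40), t_out, dt = 0.01,
                          impulse_t = 0, impulse_mass = mass)
  expect_lt(rel_err(ra, ref), 1e-4)
  # start offset delays the response
  ra2 <- meal_ra(t_out, carbs = 60, VG = 100, tauD1 = 10, tauD2 = 40,
                 t_report = 100, TD = 20)
  expect_true(all(ra2[t_out < 120] == 0))
  expect_lt(rel_err(ra2[t_out >= 120], ra[seq_len(sum(t_out >= 120))]), 1e-10)
})

test_that("insulin chain: unit DC gain, steady state, and ODE oracle with repeated poles", {
  t <- seq(0, 1440, by = 1)
  # no input, zero state -> identically zero
  expect_identical(insulin_action(t, SI_trace = 0.5), numeric(length(t)))
  # constant basal u and constant SI: X -> SI * u
  u <- 24 / 1440; SI <- 0.4
  x <- insulin_action(seq(0, 20000, by = 5), basal_rate = u, SI_trace = SI,
                      tauI1p = 16, tauI2 = 67, tauI3 = 67, tauI4 = 24)
  expect_equal(tail(x, 1), SI * u, tolerance = 1e-6)
  # single bolus through tauI2 = tauI3 = 67 (repeated pole) vs RK4 oracle
  bol <- data.frame(t_report = 0, dose = 6, TI = 0, tauI1 = 16, IA = 1)
  x <- insulin_action(t, boluses = bol, SI_trace = SI,
                      tauI1p = 16, tauI2 = 67, tauI3 = 67, tauI4 = 24)
  ref <- rk4_chain_oracle(c(16, 67, 67, 24), t, dt = 0.01, impulse_t = 0,
                          impulse_mass = 6, gain_final = SI)
  expect_lt(rel_err(x, ref), 1e-4)
  # triple-equal time constants still finite and mass-conserving
  ip <- insulin_plasma(seq(0, 20000, by = 2),
                       boluses = data.frame(t_report = 0, dose = 5,
                                            tauI1 = 50, IA = 1.2),
                       tauI2 = 50, tauI3 = 50)
  expect_true(all(is.finite(ip)))
  expect_equal(sum(ip) * 2, 1.2 * 5, tolerance = 1e-3) # DC mass = IA * dose
})

test_that("physical-activity effect follows superposed exponential decay", {
  t <- 0:2880
  expect_identical(pa_effect(t), numeric(length(t)))
  ev <- data.frame(t_report = 0, TP = 0, tauP_long = 720 / log(2),
                   tauP_short = 45, P_long = 0.4, P_short = 0.2)
  pa <- pa_effect(t, ev)
  expect_equal(pa[1], 0.6) # onset value = P_long + P_short
  # long component halves at tauP_long * ln 2
  expect_equal(pa[t == 720], 0.4 / 2 + 0.2 * exp(-720 / 45), tolerance = 1e-9)
  # 40% gain with 12 h half-time: PA at 24 h = 0.4 * 2^-2 = 0.1
  ev2 <- data.frame(t_report = 0, tauP_long = 720 / log(2), P_long = 0.4,
                    P_short = 0)
  expect_equal(pa_effect(1440, ev2), 0.1, tolerance = 1e-12)
  # overlapping events superpose
  two <- rbind(ev, transform(ev, t_report = 100))
  expect_equal(pa_effect(t, two), pa + c(numeric(100), pa[1:2781]),
               tolerance = 1e-12)
  expect_error(pa_effect(t, data.frame(t_report = 0, tauP_long = 30,
                                       tauP_short = 45)), "exceed")
})

test_that("metabolic-rate chain matches the repeated-pole closed form and clips at rest", {
  tg <- 0:720
  # heart rate at rest -> no drive
  hr_t <- seq(0, 720, by = 5)
  expect_equal(metabolic_rate(tg, hr_t, rep(65, length(hr_t)), 65),
               numeric(length(tg)))
  # below rest is clipped, not negative
  expect_equal(metabolic_rate(tg, hr_t, rep(45, length(hr_t)), 65),
               numeric(length(tg)))
  # +50 bpm step: E(t) = 50 (1 - e^(-t/tau) - (t/tau) e^(-t/tau))
  tau <- 12
  e <- metabolic_rate(tg, hr_t, rep(115, length(hr_t)), 65, tauE = tau,
                      hold_max = 10)
  # the final reading expires after hold_max: compare inside the held span
  tt <- tg[tg <= 720]
  ref <- 50 * (1 - exp(-tt / tau) - (tt / tau) * exp(-tt / tau))
  expect_lt(rel_err(e[tg <= 700], ref[tg <= 700]), 1e-9)
  # and against the generic RK4 oracle
  ref2 <- rk4_chain_oracle(c(tau, tau), tg[tg <= 700], dt = 0.01,
                           step_level = 50)
  expect_lt(rel_err(e[tg <= 700], ref2), 1e-4)
  expect_error(metabolic_rate(tg, hr_t, rep(80, length(hr_t)), -5), "positive")
})

test_that("insulin-sensitivity trace: amplitude, phase and periodicity", {
  t <- seq(0, 1440, by = 1)
  expect_equal(si_trace(t, SIE = 0.3), rep(0.3, length(t)))
  si <- si_trace(t, SIE = 1, SIA = 0.37, SIphi = 0.2)
  expect_equal(max(abs(si - 1)), 0.37, tolerance = 1e-5)
  # exact periodicity over 24 h
  t2 <- seq(0, 2880, by = 1)
  si2 <- si_trace(t2, SIE = 1, SIA = 0.3, SIphi = 0.13)
  expect_equal(si2[1:1441], si2[1441:2881], tolerance = 1e-12)
  # shifting the phase by +0.25 day moves the peak 6 h earlier
  p1 <- t[which.max(si_trace(t[-length(t)], 1, 0.3, 0.1))]
  p2 <- t[which.max(si_trace(t[-length(t)], 1, 0.3, 0.35))]
  expect_equal((p1 - p2) %% 1440, 360)
  expect_error(si_trace(t, 1, SIA = 0.7), "0.5")
})

test_that("renal excretion is the printed threshold-linear form", {
  expect_equal(renal_excretion(100), 0)
  expect_equal(renal_excretion(162), 0)
  expect_equal(renal_excretion(262), 0.3)
  # continuity and slope
  expect_lt(renal_excretion(162 + 1e-9), 1e-11)
  g <- seq(170, 400, by = 1)
  expect_equal(diff(renal_excretion(g)), rep(0.003, length(g) - 1),
               tolerance = 1e-12)
  expect_equal(renal_excretion(c(150, 200)), c(0, 0.114))
})

test_that("glucose RHS: steady state and hypoglycemia amplification", {
  # X = E = RA = 0 and G = EGP/GEZI (below renal threshold) is a fixed point
  r <- glucose_rhs(G = 150, SG = 150, X = 0, EGP = 0.3, GEZI = 0.002)
  expect_equal(r$dG, 0); expect_equal(r$dSG, 0)
  # H = 0: insulin acts with factor X alone
  r0 <- glucose_rhs(G = 60, SG = 60, X = 0.01, EGP = 0, GEZI = 0, H = 0,
                    Gth = 70)
  expect_equal(r0$dG, -0.01 * 60)
  # below Gth with H = 0.5 the insulin term is 1.5x its value above Gth
  r1 <- glucose_rhs(G = 60, SG = 60, X = 0.01, EGP = 0, GEZI = 0, H = 0.5,
                    Gth = 70)
  expect_equal(r1$dG, 1.5 * r0$dG)
  # above the threshold H is inactive
  r2 <- glucose_rhs(G = 80, SG = 80, X = 0.01, EGP = 0, GEZI = 0, H = 0.5,
                    Gth = 70)
  expect_equal(r2$dG, -0.01 * 80)
})
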