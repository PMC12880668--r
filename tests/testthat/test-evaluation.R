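# Evaluation analytics: glycemic metrics, RMSE mechanics, peak-SI period
# fractions, meal regressions and prediction-scenario plumbing.

test_that("glycemic metrics partition time exactly", {
  m <- glycemic_metrics(rep(100, 288))
  expect_equal(unlist(m), c(mean_bg = 100, tir = 100, tbr = 0, tar = 0))
  m2 <- glycemic_metrics(rep(60, 10))
  expect_equal(m2$tbr, 100)
  m3 <- glycemic_metrics(c(rep(60, 144), rep(200, 144)))
  expect_equal(m3$tbr, 50); expect_equal(m3$tar, 50)
  expect_equal(m3$mean_bg, 130)
  expect_equal(m3$tir + m3$tbr + m3$tar, 100, tolerance = 1e-9)
  # partition sums to 100 under arbitrary traces
  set.seed(2)
  for (i in 1:20) {
    g <- runif(100, 40, 350)
    mm <- glycemic_metrics(g)
    expect_equal(mm$tir + mm$tbr + mm$tar, 100, tolerance = 1e-9)
  }
})

test_that("peak-sensitivity periods follow the phase analytically", {
  # phase such that the sinusoid peaks at 04:00 -> 100% breakfast
  # peak hour h = 24 * ((1/4 - phi) mod 1)
  fit <- get_mini_fit()
  nodes <- fit$nodes
  # overwrite the guide so the phase posterior is a near point mass
  sid <- nodes$sample_ids
  tab <- nodes$table
  g <- fit$guide
  for (ph in c(4 / 24, 19 / 24)) {
    phi <- 0.25 - ph  # peak at ph * 24 hours
    g$loc[sid[["SIphi"]]] <- phi      # identity transform for phases
    g$log_d[sid[["SIphi"]]] <- log(1e-6)
    g$W[sid[["SIphi"]], ] <- 0        # no low-rank spread on the phases
    fit2 <- fit; fit2$guide <- g
    fr <- peak_si_fractions(fit2, n = 50, seed = 1)
    expect_equal(fr$n_degenerate, 0)
    if (ph == 4 / 24) expect_true(all(fr$by_patient$B == 100))
    else expect_true(all(fr$by_patient$D == 100))
    expect_true(all(abs(rowSums(fr$by_patient[, c("B", "L", "D")]) - 100) < 1e-9))
  }
  # uniform phase -> equal thirds over the three 8 h periods
  set.seed(3)
  h <- 24 * ((0.25 - runif(2e5)) %% 1)
  bin <- ifelse(h > 2 & h <= 10, "B", ifelse(h > 10 & h <= 18, "L", "D"))
  expect_lt(max(abs(table(bin) / 2e5 - 1 / 3)), 0.01)
})

test_that("posterior-predictive RMSE recovers trivial cases", {
  fit <- get_mini_fit()
  coh <- get_mini_cohort()
  # predictive mean identical to CGM -> RMSE 0; constant offset -> |offset|
  mu <- predictive_mean_at(
    posterior_predictive(fit, coh$samples, n = 20, seed = 1),
    lapply(coh$samples, function(s) s$cgm$t))
  fake <- coh$samples
  for (s in seq_along(fake)) fake[[s]]$cgm$glucose <- mu[[s]]
  r0 <- rmse_posterior_mean(fit, fake, n = 20, seed = 1, n_boot = 200)
  expect_lt(max(r0$by_window$rmse), 1e-9)
  for (s in seq_along(fake)) fake[[s]]$cgm$glucose <- mu[[s]] + 7
  r7 <- rmse_posterior_mean(fit, fake, n = 20, seed = 1, n_boot = 200)
  expect_equal(r7$by_window$rmse, rep(7, 4), tolerance = 1e-9)
  expect_true(all(r7$by_patient$ci_lo <= r7$by_patient$rmse + 1e-12))
  expect_true(all(r7$by_patient$ci_hi >= r7$by_patient$rmse - 1e-12))
})

test_that("meal OLS: duplication invariance and planted-effect recovery", {
  set.seed(9)
  n <- 120
  d <- data.frame(carbs = runif(n, 20, 120), fat = runif(n, 0, 40),
                  protein = runif(n, 0, 40), dCGM = runif(n, 60, 260))
  d$tauD2 <- 48 + 0.1 * d$carbs + rnorm(n, 0, 4)
  f1 <- lm(tauD2 ~ carbs + fat + protein + dCGM, d)
  ci <- confint(f1)["carbs", ]
  expect_true(ci[1] <= 0.1 && 0.1 <= ci[2])
  # duplicating rows leaves coefficients unchanged, shrinks p-values
  d2 <- rbind(d, d)
  f2 <- lm(tauD2 ~ carbs + fat + protein + dCGM, d2)
  expect_equal(coef(f2), coef(f1), tolerance = 1e-10)
  p1 <- summary(f1)$coefficients["fat", 4]
  p2 <- summary(f2)$coefficients["fat", 4]
  expect_lt(p2, p1)
  # the package's wrapper refuses tiny meal sets and reports all three tables
  fit <- get_mini_fit()
  coh <- get_mini_cohort()
  ols <- posthoc_meal_regression(fit, coh$samples, n = 50, seed = 2)
  for (nm in c("tauD2", "TD", "MA")) {
    expect_true(all(c("coef", "p", "ci_lo", "ci_hi") %in% names(ols[[nm]])))
    expect_equal(nrow(ols[[nm]]), 5)
  }
  expect_error(posthoc_meal_regression(fit, coh$samples[1], n = 10, seed = 1),
               "at least 10")
})

test_that("null meal effects are covered by the OLS interval at the right rate", {
  # with tauD2 independent of the macros, the carb coefficient's 95% CI
  # should contain zero in nearly all replicates
  set.seed(31)
  hit <- 0
  for (k in 1:40) {
    n <- 60
    d <- data.frame(carbs = runif(n, 20, 120), fat = runif(n, 0, 40),
                    protein = runif(n, 0, 40), dCGM = runif(n, 60, 260),
                    tauD2 = 48 + rnorm(n, 0, 6))
    ci <- confint(lm(tauD2 ~ carbs + fat + protein + dCGM, d))["carbs", ]
    if (ci[1] <= 0 && 0 <= ci[2]) hit <- hit + 1
  }
  expect_gte(hit / 40, 0.9)
})

test_that("prediction scenarios: definitions and origin eligibility", {
  s1 <- prediction_scenario(1)
  expect_equal(unname(s1$blank), c(45, 120, 1440))
  expect_false(s1$require_absent)
  s3 <- prediction_scenario(3)
  expect_true(s3$require_absent)
  expect_error(prediction_scenario(4), "1, 2 or 3")
  # a window dense with events leaves scenario 3 with no origins
  fit <- get_mini_fit()
  coh <- get_mini_cohort()
  dense <- coh$samples[1]
  dense[[1]]$meals <- data.frame(t = seq(10, 1430, by = 30),
                                 carbs = 30, fat = 5, protein = 5)
  # hierarchy no longer matches -> use the original windows for the real
  # call; here only the empty-result contract matters
  r3 <- prediction_eval(fit, coh$samples, scenario = 3, n = 4, seed = 1)
  expect_true(is.data.frame(r3))
  expect_equal(r3$horizon, c(30, 60))
  r1 <- prediction_eval(fit, coh$samples, scenario = 1, n = 4, seed = 1)
  expect_true(all(r1$n_origins >= r3$n_origins))
})
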