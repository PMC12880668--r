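# Hierarchy structure, prior sampling, the EGP-SI linkage, transforms and
# the joint density.

test_that("node table matches the level map of the hierarchy", {
  hier <- vp_hierarchy(2, c(2, 3), n_meals = 2, n_boluses = 1, n_exercise = 1)
  nodes <- build_nodes(hier)
  tab <- nodes$table
  # every prior-table latent appears at exactly its declared levels
  pri <- vp_priors()
  for (i in seq_len(nrow(pri))) {
    n_exp <- switch(pri$level[i], cohort = 1, patient = 2, sample = 5,
                    meal = 10, bolus = 5, exercise = 5)
    n_got <- sum(tab$latent == pri$latent[i] & tab$level == pri$level[i])
    expect_equal(n_got, n_exp, label = paste(pri$latent[i], pri$level[i]))
  }
  # three-level latents: patient values shared across that patient's windows
  expect_equal(length(unique(tab$loc_a[tab$latent == "SIE" &
                                         tab$level == "sample" &
                                         tab$patient == 2])), 1)
  # slot maps: two windows of one patient share VG but have distinct SIE
  m1 <- nodes$slot_map[[1]]; m2 <- nodes$slot_map[[2]]
  expect_identical(m1[1], m2[1])          # VG (patient level)
  expect_false(m1[4] == m2[4])            # SIE (window level)
  expect_false(m1[3] == m2[3])            # EGP (window level)
  # event-level MA differs between two meals of one window
  ma <- which(tab$latent == "MA" & tab$sample == 1)
  expect_equal(length(ma), 2)
  expect_false(ma[1] == ma[2])
})

test_that("prior draws respect every support and reuse parent values", {
  hier <- vp_hierarchy(1, 1, n_meals = 1, n_boluses = 1, n_exercise = 1)
  nodes <- build_nodes(hier)
  d <- sample_latents(nodes, n = 2000, seed = 1)
  tab <- nodes$table
  expect_true(all(d$z >= tab$lower & d$z <= tab$upper))
  # degenerate hierarchy: one patient, one window -> patient latents are
  # the location of the window's distribution
  i_sie_s <- which(tab$latent == "SIE" & tab$level == "sample")
  expect_equal(tab$loc_a[i_sie_s],
               which(tab$latent == "SIE" & tab$level == "patient"))
  # Monte-Carlo means of the scale priors match their closed forms
  i_exp <- which(tab$family == "expo")[1]
  expect_equal(mean(d$z[i_exp, ]), tab$loc_const[i_exp], tolerance = 0.05)
  # truncated draws stay strictly inside their bounds over many draws
  i_tn <- which(tab$family == "tnorm")
  expect_true(all(d$z[i_tn, ] >= tab$lower[i_tn]))
  expect_true(all(d$z[i_tn, ] <= tab$upper[i_tn]))
})

test_that("EGP-SI linkage has the sign of EGPm and degenerates correctly", {
  expect_equal(egp_for_sample(1, 2, 0.3, 0), 1.6)
  expect_equal(egp_for_sample(1, 0, 0.3, 0), 1)
  set.seed(3)
  sie <- runif(4000, 0.1, 0.6)
  egp_pos <- vapply(sie, function(x) egp_for_sample(0.5, 3, x, 0.2), 0)
  egp_zero <- vapply(sie, function(x) egp_for_sample(0.5, 0, x, 0.2), 0)
  expect_gt(cor(sie, egp_pos), 0.5)
  expect_lt(abs(cor(sie, egp_zero)), 0.05)
  expect_error(egp_for_sample(-1, 0, 0.3, 0.1), "non-negative")
  expect_error(egp_for_sample(1, 0, 0.3, -0.1), "non-negative")
})

test_that("log_joint equals a hand-summed density on a 3-point toy window", {
  # zero-input fixed point: SG is constant, so the likelihood is three
  # independent normal terms that we can write down by hand
  G0 <- 150
  s <- sample24h(cgm = data.frame(t = c(0, 300, 600), glucose = c(G0, 155, 147)),
                 basal = 0, hr_rest = 60)
  s$t_end <- 1440
  hier <- hierarchy_from_samples(list(s), "p1")
  nodes <- build_nodes(hier)
  z <- glucopop:::prior_median(nodes)
  tab <- nodes$table
  set0 <- function(lat, lev, val) {
    i <- tab$latent == lat & tab$level %in% lev
    z[i] <<- val
  }
  set0("X0", c("cohort", "patient", "sample"), 0)
  set0("S0", c("cohort", "patient", "sample"), 0)
  set0("Ip0", c("cohort", "patient", "sample"), 0)
  set0("SIA", c("cohort", "patient", "sample"), 0)
  set0("SE", c("cohort", "patient"), 0)
  # EGP = GEZI * G0 exactly balances production
  gezi <- unname(z[tab$latent == "GEZI" & tab$level == "patient"])
  set0("EGP", "sample", gezi * G0)
  sig <- unname(z[tab$latent == "sigma" & tab$level == "sample"])
  lj <- log_joint(z, nodes, list(s), grid_dt = 1)
  hand_lik <- sum(dnorm(c(G0, 155, 147), G0, sig, log = TRUE))
  hand_prior <- glucopop:::log_prior(z, nodes)
  expect_equal(lj, hand_prior + hand_lik, tolerance = 1e-10)
  # a single CGM point equal to the simulated SG contributes -log(sigma*sqrt(2*pi))
  s1 <- s; s1$cgm <- data.frame(t = 0, glucose = G0)
  lj1 <- log_joint(z, nodes, list(s1), grid_dt = 1)
  expect_equal(lj1 - hand_prior, -log(sig * sqrt(2 * pi)), tolerance = 1e-10)
  # doubling sigma at fixed residuals changes the likelihood by the
  # closed-form amount
  z2 <- z
  z2[tab$latent == "sigma" & tab$level == "sample"] <- 2 * sig
  lj2 <- log_joint(z2, nodes, list(s), grid_dt = 1)
  r2 <- sum((c(G0, 155, 147) - G0)^2)
  dlik <- (-3 * log(2 * sig) - r2 / (2 * 4 * sig^2)) -
    (-3 * log(sig) - r2 / (2 * sig^2))
  dprior <- glucopop:::log_prior(z2, nodes) - hand_prior
  expect_equal(lj2 - lj, dlik + dprior, tolerance = 1e-10)
  # out-of-support latents give -Inf, not an error
  z3 <- z; z3[tab$latent == "VG" & tab$level == "cohort"] <- 1e9
  expect_identical(log_joint(z3, nodes, list(s)), -Inf)
})

test_that("transforms are bijective with correct Jacobians", {
  nodes <- build_nodes(vp_hierarchy(1, 2, 2, 1, 1))
  z <- sample_latents(nodes, 1, seed = 5)$z[, 1]
  u <- transform_latents(z, nodes)
  expect_equal(untransform_latents(u, nodes), z, tolerance = 1e-10,
               ignore_attr = TRUE)
  # midpoint of a truncated latent round-trips exactly
  tab <- nodes$table
  i <- which(tab$transform == "logit")[1]
  zm <- z; zm[i] <- (tab$lower[i] + tab$upper[i]) / 2
  expect_equal(untransform_latents(transform_latents(zm, nodes), nodes)[i],
               zm[i], tolerance = 1e-12, ignore_attr = TRUE)
  # monotone on a grid
  zg <- sapply(seq(-5, 5, by = 0.5), function(v) {
    uu <- u; uu[i] <- v; untransform_latents(uu, nodes)[i]
  })
  expect_true(all(diff(zg) > 0))
  # log-Jacobian matches finite differences of the volume element
  h <- 1e-6
  for (j in c(i, which(tab$transform == "log_lb")[1])) {
    up <- u; up[j] <- u[j] + h
    num <- (untransform_latents(up, nodes)[j] - z[j]) / h
    lj <- log_jacobian(u, nodes)
    ljp <- log_jacobian(up, nodes)
    expect_true(is.finite(lj))
    # d(logJ)/du against the analytic gradient used in fitting
    expect_equal((ljp - lj) / h, glucopop:::.jac_grad(u, nodes)[j],
                 tolerance = 1e-4)
    expect_gt(num, 0)
  }
  # boundary values map to large finite numbers, never NaN
  zb <- z; zb[i] <- tab$lower[i]
  ub <- transform_latents(zb, nodes)
  expect_true(is.finite(ub[i]))
})

test_that("assemble/scatter round-trips slot-covered latents", {
  hier <- vp_hierarchy(2, 2, n_meals = 2, n_boluses = 2, n_exercise = 1)
  nodes <- build_nodes(hier)
  d <- sample_latents(nodes, 1, seed = 8)
  asm <- assemble_sample_params(d, nodes, 3)
  expect_s3_class(asm$params, "sim_params")
  expect_equal(nrow(asm$meals), 2)
  expect_equal(nrow(asm$exercise), 1)
  slots <- lapply(seq_len(4), function(s) d$z[nodes$slot_map[[s]], 1])
  z2 <- scatter_sample_params(slots, nodes)
  cov <- !is.na(z2)
  expect_equal(z2[cov], d$z[cov, 1], ignore_attr = TRUE)
  # patient-level values shared across that patient's two windows
  expect_identical(slots[[1]][1], slots[[2]][1])  # VG
  expect_error(assemble_sample_params(d, nodes, 99))
})

test_that("the effective prior table round-trips through CSV", {
  pri <- vp_priors()
  f <- tempfile(fileext = ".csv")
  write_priors(pri, f)
  pri2 <- read_priors(f)
  expect_equal(as.data.frame(pri2), as.data.frame(pri), tolerance = 1e-12)
  expect_true(all(c("literature", "default") %in% pri2$source))
  # a modified table still builds a consistent hierarchy
  pri2$scale[pri2$latent == "MA"] <- 0.25
  nodes <- build_nodes(vp_hierarchy(1, 1, 1, 1, 0), pri2)
  expect_equal(nodes$table$scale_const[nodes$table$latent == "MA"], 0.25)
  expect_error(suppressWarnings(read_priors(tempfile())))
})
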