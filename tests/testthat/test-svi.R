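# The variational machinery: ELBO identities, guide algebra, seeding,
# gradients of the model closure.

test_that("ELBO is zero when guide equals model and estimates are seeded", {
  m <- list(D = 2L, f = function(u) sum(dnorm(u, log = TRUE)))
  g <- glucopop:::guide_state(c(0, 0), c(0, 0), NULL)
  e <- elbo_estimate(g, m, n_particles = 2000, seed = 2)
  expect_lt(abs(e), 0.05)
  # fixed seed -> identical estimate
  expect_identical(elbo_estimate(g, m, 500, seed = 9),
                   elbo_estimate(g, m, 500, seed = 9))
  # guide shifted by delta from a standard-normal target: deficit ~ delta^2/2
  d <- 0.7
  gd <- glucopop:::guide_state(c(d, 0), c(0, 0), NULL)
  ed <- elbo_estimate(gd, m, 4000, seed = 3)
  expect_lt(abs(ed + d^2 / 2), 0.05)
  # non-finite particles are dropped with a warning
  mbad <- list(D = 1L, f = function(u) if (u > 0) -Inf else dnorm(u, log = TRUE))
  gb <- glucopop:::guide_state(0, 0, NULL)
  expect_warning(elbo_estimate(gb, mbad, 50, seed = 1), "non-finite")
})

test_that("low-rank guide algebra: density, entropy and sampling agree", {
  set.seed(4)
  D <- 6; r <- 2
  g <- glucopop:::guide_state(rnorm(D), rnorm(D, -1, 0.3),
                              matrix(rnorm(D * r, 0, 0.5), D, r))
  d <- exp(g$log_d)
  Sig <- diag(d^2) + tcrossprod(g$W)
  # log-density against the explicit multivariate normal formula
  u <- rnorm(D)
  ld_ref <- -0.5 * (D * log(2 * pi) + determinant(Sig)$modulus +
                      t(u - g$loc) %*% solve(Sig) %*% (u - g$loc))
  expect_equal(glucopop:::guide_logdens(g, u), as.numeric(ld_ref),
               tolerance = 1e-10)
  # entropy against the closed form
  expect_equal(glucopop:::guide_entropy(g),
               0.5 * D * (1 + log(2 * pi)) +
                 0.5 * as.numeric(determinant(Sig)$modulus),
               tolerance = 1e-10)
  # empirical covariance of many draws matches diag^2 + W W^T
  set.seed(5)
  U <- glucopop:::guide_sample(g, 1e5)$U
  emp <- cov(t(U))
  expect_lt(norm(emp - Sig, "F") / norm(Sig, "F"), 0.03)
  # entropy gradient against finite differences
  eg <- glucopop:::.entropy_grad(g)
  h <- 1e-6
  for (i in c(1, D)) {
    gp <- g; gp$log_d[i] <- g$log_d[i] + h
    expect_equal((glucopop:::guide_entropy(gp) - glucopop:::guide_entropy(g)) / h,
                 eg$log_d[i], tolerance = 1e-4)
  }
  gp <- g; gp$W[3, 1] <- g$W[3, 1] + h
  expect_equal((glucopop:::guide_entropy(gp) - glucopop:::guide_entropy(g)) / h,
               eg$W[3, 1], tolerance = 1e-4)
})

test_that("a rank-0 guide is exactly mean-field", {
  set.seed(6)
  D <- 4
  g0 <- glucopop:::guide_state(rnorm(D), rnorm(D, -1, 0.2),
                               matrix(0, D, 0))
  u <- rnorm(D)
  expect_equal(glucopop:::guide_logdens(g0, u),
               sum(dnorm(u, g0$loc, exp(g0$log_d), log = TRUE)),
               tolerance = 1e-12)
  # and a rank-2 guide with W = 0 equals the same mean-field density
  gz <- glucopop:::guide_state(g0$loc, g0$log_d, matrix(0, D, 2))
  expect_equal(glucopop:::guide_logdens(gz, u),
               glucopop:::guide_logdens(g0, u), tolerance = 1e-12)
})

test_that("fit_svi is deterministic given the seed and records a full ELBO trace", {
  m <- list(D = 1L,
            f_grad = function(u) list(value = -0.5 * sum((u - 3)^2),
                                      grad = -(u - 3)))
  c1 <- svi_config(n_particles = 3, n_iterations = 200, rank = 0, seed = 5,
                   lr = 0.05, lr_end = 0.005)
  f1 <- fit_svi(m, c1)
  f2 <- fit_svi(m, c1)
  expect_identical(f1$guide$loc, f2$guide$loc)
  expect_identical(f1$elbo, f2$elbo)
  expect_length(f1$elbo, 200)
})

test_that("checkpoint and resume reproduce an uninterrupted fit's endpoint", {
  m <- list(D = 2L,
            f_grad = function(u) list(value = -0.5 * sum(u^2), grad = -u))
  f_full <- fit_svi(m, svi_config(n_particles = 2, n_iterations = 100,
                                  rank = 0, seed = 8, lr = 0.05))
  # same run, but leaving a checkpoint at iteration 60
  ck <- tempfile(fileext = ".rds")
  fit_svi(m, svi_config(n_particles = 2, n_iterations = 100, rank = 0,
                        seed = 8, lr = 0.05, checkpoint = ck,
                        checkpoint_every = 60))
  f_res <- fit_svi(m, svi_config(n_particles = 2, n_iterations = 100,
                                 rank = 0, seed = 8, lr = 0.05, resume = ck))
  # identical up to the checkpoint; afterwards the RNG stream differs but
  # the optimum does not
  expect_equal(f_res$elbo[1:60], f_full$elbo[1:60])
  expect_length(f_res$elbo, 100)
  expect_lt(max(abs(f_res$guide$loc)), max(0.15, max(abs(f_full$guide$loc)) * 3))
})

test_that("posterior draws respect supports; n = 0 gives empty draws", {
  fit <- get_mini_fit()
  d <- sample_posterior(fit, 200, seed = 4)
  tab <- fit$nodes$table
  expect_true(all(d$z >= tab$lower & d$z <= tab$upper))
  d0 <- sample_posterior(fit, 0)
  expect_equal(ncol(d0$z), 0)
  # seeded reproducibility
  expect_identical(sample_posterior(fit, 5, seed = 3)$z,
                   sample_posterior(fit, 5, seed = 3)$z)
})

test_that("the glucose model's gradient matches finite differences of f", {
  coh <- get_mini_cohort()
  m <- vp_model(coh$samples, nodes = coh$nodes, grid_dt = 5)
  set.seed(10)
  u0 <- m$init_loc + rnorm(m$D, 0, 0.05)
  fg <- m$f_grad(u0)
  expect_equal(fg$value, m$f(u0), tolerance = 1e-10)
  idx <- sort(sample(m$D, 8))
  num <- vapply(idx, function(j) {
    h <- 1e-5
    up <- u0; up[j] <- u0[j] + h
    um <- u0; um[j] <- u0[j] - h
    (m$f(up) - m$f(um)) / (2 * h)
  }, 0)
  expect_equal(fg$grad[idx], num, tolerance = 1e-3)
})

test_that("smoothed ELBO is non-decreasing over the back half of a mini fit", {
  fit <- get_mini_fit()
  el <- fit$elbo
  sm <- stats::filter(el, rep(1 / 50, 50), sides = 1)
  back <- sm[!is.na(sm)]
  back <- back[(length(back) %/% 2):length(back)]
  # monotone trend: the last smoothed value tops the half-way value and
  # dips are small relative to the total climb
  expect_gt(tail(back, 1), back[1] - 0.01 * abs(back[1]))
})
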