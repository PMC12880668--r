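# Stochastic variational inference with a low-rank multivariate normal
# guide on the unconstrained latent space. The guide covariance is
# diag(d)^2 + W W^T with W of rank r; r = 0 is exactly a mean-field normal
# guide. Gradients of the likelihood come from the compiled engine
# (finite differences over each window's parameter slots); gradients of
# the hierarchical prior and the transform Jacobian are analytic.

# ---- prior gradient --------------------------------------------------------

# value and gradient (constrained space) of the prior log density
log_prior_grad <- function(z, nodes) {
  tab <- nodes$table
  D <- nrow(tab)
  ls <- .resolve_loc_scale(z, tab)
  m <- ls$loc[, 1]; s <- ls$scale[, 1]
  x <- z
  val <- numeric(D); dldx <- numeric(D); dldm <- numeric(D); dlds <- numeric(D)
  for (fam in unique(tab$family)) {
    i <- which(tab$family == fam)
    xi <- x[i]; mi <- m[i]; si <- s[i]
    li <- tab$lower[i]; ui <- tab$upper[i]
    if (fam %in% c("tnorm", "norm")) {
      r <- (xi - mi) / si
      if (fam == "tnorm") {
        a <- (li - mi) / si; b <- (ui - mi) / si
        pa <- pnorm(a); pb <- pnorm(b); da <- dnorm(a); db <- dnorm(b)
        dP <- pb - pa
        val[i] <- dnorm(xi, mi, si, log = TRUE) - log(dP)
        val[i][xi < li | xi > ui] <- -Inf
        dldx[i] <- -r / si
        dldm[i] <- r / si + (db - da) / (si * dP)
        dlds[i] <- (r^2 - 1) / si + (b * db - a * da) / (si * dP)
      } else {
        val[i] <- dnorm(xi, mi, si, log = TRUE)
        dldx[i] <- -r / si
        dldm[i] <- r / si
        dlds[i] <- (r^2 - 1) / si
      }
    } else if (fam == "lnorm") {
      ok <- xi > 0
      lx <- ifelse(ok, log(xi), 0)
      r <- (lx - mi) / si
      val[i] <- ifelse(ok, dnorm(lx, mi, si, log = TRUE) - lx, -Inf)
      dldx[i] <- ifelse(ok, (-r / si - 1) / xi, 0)
      dldm[i] <- ifelse(ok, r / si, 0)
      dlds[i] <- ifelse(ok, (r^2 - 1) / si, 0)
    } else if (fam == "unif") {
      val[i] <- ifelse(xi >= li & xi <= ui, -log(ui - li), -Inf)
    } else if (fam == "expo") {
      val[i] <- ifelse(xi >= 0, -xi / mi - log(mi), -Inf)
      dldx[i] <- ifelse(xi >= 0, -1 / mi, 0)
      dldm[i] <- ifelse(xi >= 0, xi / mi^2 - 1 / mi, 0)
    } else if (fam == "halfnorm") {
      val[i] <- ifelse(xi >= 0, log(2) + dnorm(xi, 0, si, log = TRUE), -Inf)
      dldx[i] <- ifelse(xi >= 0, -xi / si^2, 0)
      dlds[i] <- ifelse(xi >= 0, (xi^2 / si^2 - 1) / si, 0)
    }
  }
  g <- dldx
  acc <- function(g, idx, v) {
    if (!length(idx)) return(g)
    a <- rowsum(v, idx)
    ii <- as.integer(rownames(a))
    g[ii] <- g[ii] + a[, 1]
    g
  }
  ip <- which(tab$loc_mode == "parent")
  if (length(ip)) {
    w <- ifelse(tab$family[ip] == "lnorm", 1 / z[tab$loc_a[ip]], 1)
    g <- acc(g, tab$loc_a[ip], dldm[ip] * w)
  }
  ie <- which(tab$loc_mode == "egp")
  if (length(ie)) {
    g <- acc(g, tab$loc_a[ie], dldm[ie])
    g <- acc(g, tab$loc_b[ie], dldm[ie] * z[tab$loc_c[ie]])
    g <- acc(g, tab$loc_c[ie], dldm[ie] * z[tab$loc_b[ie]])
  }
  isc <- which(tab$scale_mode == "node")
  if (length(isc)) g <- acc(g, tab$scale_id[isc], dlds[isc])
  list(value = sum(val), grad = g)
}

# d(log-Jacobian)/du, elementwise
.jac_grad <- function(u, nodes) {
  tab <- nodes$table
  gj <- numeric(length(u))
  i <- tab$transform == "logit"
  if (any(i)) gj[i] <- 1 - 2 * plogis(u[i])
  i <- tab$transform == "log_lb"
  if (any(i)) gj[i] <- 1
  gj
}

# ---- the glucose model as an SVI target ------------------------------------

#' Build the SVI target for a prepared cohort
#'
#' Packages the hierarchical log-joint (priors + CGM likelihood over all
#' windows) and its gradient in unconstrained space as the objective
#' consumed by [fit_svi()].
#'
#' @param samples list of [sample24h()] windows in patient-major order.
#' @param priors a [vp_priors()] table.
#' @param nodes optional pre-built [build_nodes()]; built from the samples
#'   otherwise.
#' @param patient_ids patient per window (defaults to the windows' ids).
#' @param grid_dt simulation grid step for the likelihood (min); 5 min
#'   (the CGM cadence) is the fitting default.
#' @return a model object (list with `D`, `f`, `f_grad`, `init_loc`,
#'   `nodes`, ...).
#' @export
vp_model <- function(samples, priors = vp_priors(), nodes = NULL,
                     patient_ids = NULL, grid_dt = 5) {
  if (is.null(nodes))
    nodes <- build_nodes(hierarchy_from_samples(samples, patient_ids), priors)
  ed <- prepare_engine_data(samples)
  tab <- nodes$table
  D <- nrow(tab)
  fd_list <- lapply(nodes$slot_map, function(m) tab$fd[m])
  f <- function(u) {
    z <- untransform_latents(u, nodes)
    lp <- log_prior(z, nodes)
    if (!is.finite(lp)) return(-Inf)
    slots <- lapply(nodes$slot_map, function(m) z[m])
    lp + log_jacobian(u, nodes) + cpp_loglik_batch(slots, ed, grid_dt)
  }
  f_grad <- function(u) {
    z <- untransform_latents(u, nodes)
    slots <- lapply(nodes$slot_map, function(m) z[m])
    lik <- cpp_loglik_grad_batch(slots, ed, grid_dt, fd_list)
    if (!isTRUE(lik$finite))
      return(list(value = -Inf, grad = numeric(D)))
    gz <- numeric(D)
    for (s in seq_along(slots)) {
      map <- nodes$slot_map[[s]]
      gz[map] <- gz[map] + lik$grads[[s]]
    }
    pr <- log_prior_grad(z, nodes)
    dz <- .dz_du(u, nodes)
    list(value = lik$value + pr$value + log_jacobian(u, nodes),
         grad = (gz + pr$grad) * dz + .jac_grad(u, nodes))
  }
  per_sample_lik <- function(u) {
    z <- untransform_latents(u, nodes)
    vapply(seq_along(ed), function(s)
      cpp_loglik(z[nodes$slot_map[[s]]], ed[[s]], grid_dt), 0)
  }
  zmed <- profile_init(nodes, samples, ed, grid_dt)
  list(D = D, f = f, f_grad = f_grad, nodes = nodes, engine_data = ed,
       grid_dt = grid_dt, samples = samples,
       init_loc = transform_latents(zmed, nodes),
       per_sample_lik = per_sample_lik)
}

# Initialization by coordinate profiling. Starting from cascaded prior
# medians, each window's few genuinely coupled coordinates are placed by
# coarse likelihood profiles before any gradient step:
#   * the sinusoid phase (the model's one multimodal direction: from a
#     wrong phase, gradient ascent collapses the amplitude into a local
#     basin it cannot leave), then the amplitude;
#   * the (SIE, EGP) pair along its mass-balance ridge: for each
#     candidate sensitivity, EGP is set to the window's glucose balance
#     EGP = (GEZI + SIE * mean insulin) * mean G + renal - meal
#     appearance, and the likelihood picks the position on the ridge.
# Parents are then set to the means of their children. Everything here
# uses only the observed window data and prior-median kinetics.
profile_init <- function(nodes, samples, ed, grid_dt) {
  tab <- nodes$table
  zmed <- prior_median(nodes)
  sid <- nodes$sample_ids
  pid <- nodes$patient_ids
  balance <- function(s, sie) {
    smp <- samples[[s]]
    p <- nodes$hier$sample_patient[s]
    gbar <- mean(smp$cgm$glucose)
    ip_bar <- smp$basal + sum(smp$boluses$dose) / smp$t_end
    gezi <- zmed[pid[["GEZI"]][p]]
    vg <- zmed[pid[["VG"]][p]]
    ra_bar <- 0.8 * sum(smp$meals$carbs) * 1000 / (vg * smp$t_end)
    fr_bar <- 0.003 * max(gbar - 162, 0)
    unname((gezi + sie * ip_bar) * gbar + fr_bar - ra_bar)
  }
  iegp <- sid[["EGP"]]; isie <- sid[["SIE"]]
  isia <- sid[["SIA"]]; iphi <- sid[["SIphi"]]
  clamp <- function(v, i) min(max(v, tab$lower[i] + 1e-3),
                              tab$upper[i] - 1e-3)
  ll_of <- function(z, s) cpp_loglik(z[nodes$slot_map[[s]]], ed[[s]], grid_dt)
  for (s in seq_along(ed)) {
    zmed[iegp[s]] <- clamp(balance(s, zmed[isie[s]]), iegp[s])
    prof <- function(i, cand, egp_track = FALSE) {
      ll <- vapply(cand, function(v) {
        zz <- zmed
        zz[i] <- v
        if (egp_track) zz[iegp[s]] <- clamp(balance(s, v), iegp[s])
        ll_of(zz, s)
      }, 0)
      best <- cand[which.max(ll)]
      zmed[i] <<- best
      if (egp_track) zmed[iegp[s]] <<- clamp(balance(s, best), iegp[s])
    }
    for (round in 1:2) {
      prof(iphi[s], seq(0, 0.875, by = 0.125))
      prof(isia[s], c(0.05, 0.15, 0.25, 0.35, 0.45))
      prof(isie[s], c(0.08, 0.15, 0.25, 0.35, 0.5, 0.7), egp_track = TRUE)
    }
  }
  # parents at the (circular for phases) means of their children
  circ_mean <- function(x) (atan2(mean(sin(2 * pi * x)),
                                  mean(cos(2 * pi * x))) / (2 * pi)) %% 1
  for (lat in c("SIE", "SIA", "SIphi")) {
    for (p in seq_len(nodes$hier$n_patients)) {
      ws <- which(nodes$hier$sample_patient == p)
      v <- zmed[sid[[lat]][ws]]
      i <- pid[[lat]][p]
      zmed[i] <- if (lat == "SIphi") circ_mean(v) else clamp(mean(v), i)
    }
    i <- nodes$cohort_ids[[lat]]
    v <- zmed[pid[[lat]]]
    zmed[i] <- if (lat == "SIphi") min(max(circ_mean(v), 0.02), 0.98)
               else clamp(mean(v), i)
  }
  zmed
}

# prior medians cascaded down the hierarchy
prior_median <- function(nodes) {
  tab <- nodes$table
  z <- numeric(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    m <- switch(tab$loc_mode[i],
                const = tab$loc_const[i],
                parent = if (tab$family[i] == "lnorm") log(z[tab$loc_a[i]])
                         else z[tab$loc_a[i]],
                egp = z[tab$loc_a[i]] + z[tab$loc_b[i]] * z[tab$loc_c[i]])
    s <- if (tab$scale_mode[i] == "node") z[tab$scale_id[i]] else tab$scale_const[i]
    z[i] <- switch(tab$family[i],
      tnorm = {
        pa <- pnorm(tab$lower[i], m, s); pb <- pnorm(tab$upper[i], m, s)
        qnorm((pa + pb) / 2, m, s)
      },
      norm = m,
      lnorm = exp(m),
      unif = (tab$lower[i] + tab$upper[i]) / 2,
      expo = m * log(2),
      halfnorm = s * qnorm(0.75))
  }
  names(z) <- tab$name
  z
}

# ---- the low-rank multivariate normal guide --------------------------------

guide_state <- function(loc, log_d, W) {
  structure(list(loc = loc, log_d = log_d, W = W,
                 D = length(loc), r = if (is.null(W)) 0L else ncol(W)),
            class = "guide_state")
}

#' @export
print.guide_state <- function(x, ...) {
  cat(sprintf("<guide_state> low-rank MVN, D = %d, rank = %d\n", x$D, x$r))
  invisible(x)
}

# Woodbury pieces for Sigma = diag(d^2) + W W^T
.guide_chol <- function(d, W) {
  if (is.null(W) || ncol(W) == 0) return(NULL)
  Wd <- W / d^2
  A <- crossprod(W, Wd)
  diag(A) <- diag(A) + 1
  list(Wd = Wd, cA = chol(A))
}

.guide_logdet <- function(d, wb) {
  v <- 2 * sum(log(d))
  if (!is.null(wb)) v <- v + 2 * sum(log(diag(wb$cA)))
  v
}

.sigma_inv_mult <- function(x, d, wb) {
  y <- x / d^2
  if (is.null(wb)) return(y)
  t <- crossprod(wb$Wd, x)
  y - wb$Wd %*% backsolve(wb$cA, backsolve(wb$cA, t, transpose = TRUE))
}

guide_sample <- function(guide, n) {
  d <- exp(guide$log_d)
  eps <- matrix(rnorm(guide$D * n), guide$D, n)
  U <- guide$loc + d * eps
  eta <- NULL
  if (guide$r > 0) {
    eta <- matrix(rnorm(guide$r * n), guide$r, n)
    U <- U + guide$W %*% eta
  }
  list(U = U, eps = eps, eta = eta)
}

guide_logdens <- function(guide, U) {
  U <- cbind(U)
  d <- exp(guide$log_d)
  wb <- .guide_chol(d, if (guide$r > 0) guide$W else NULL)
  ld <- .guide_logdet(d, wb)
  dx <- U - guide$loc
  qf <- colSums(dx * apply(dx, 2, .sigma_inv_mult, d = d, wb = wb))
  unname(drop(-0.5 * (guide$D * log(2 * pi) + ld + qf)))
}

guide_entropy <- function(guide) {
  d <- exp(guide$log_d)
  wb <- .guide_chol(d, if (guide$r > 0) guide$W else NULL)
  0.5 * guide$D * (1 + log(2 * pi)) + 0.5 * .guide_logdet(d, wb)
}

# gradient of the entropy wrt (log_d, W)
.entropy_grad <- function(guide) {
  d <- exp(guide$log_d)
  W <- if (guide$r > 0) guide$W else NULL
  wb <- .guide_chol(d, W)
  if (is.null(wb)) {
    return(list(log_d = rep(1, guide$D), W = NULL))
  }
  SiW <- apply(W, 2, .sigma_inv_mult, d = d, wb = wb)
  # diag(Sigma^-1) = 1/d^2 - rowSums((Wd %*% A^-1) * Wd)
  WdA <- t(backsolve(wb$cA, backsolve(wb$cA, t(wb$Wd), transpose = TRUE)))
  diagSi <- 1 / d^2 - rowSums(WdA * wb$Wd)
  list(log_d = d^2 * diagSi, W = SiW)
}

#' SVI configuration
#'
#' Defaults mirror the reference fitting setup: 15 Monte Carlo particles
#' for the ELBO gradient and 80,000 iterations; Adam with a cosine decay
#' from `lr` to `lr_end`; guide rank `min(50, D)` unless given.
#'
#' @param n_particles ELBO particles per iteration (>= 1).
#' @param n_iterations optimization steps (>= 1).
#' @param lr,lr_end initial and final Adam learning rate.
#' @param rank guide rank (0 = mean-field); `NULL` for `min(50, D)`.
#' @param rank_warmup iterations during which the low-rank factor stays
#'   frozen at zero (exactly mean-field); activating the covariance factor
#'   only after the means have settled speeds convergence on short runs.
#' @param seed RNG seed (the whole fit is deterministic given it).
#' @param grad_clip global gradient-norm clip.
#' @param checkpoint optional RDS path written every `checkpoint_every`
#'   iterations; `resume` restarts from such a file.
#' @param checkpoint_every iterations between checkpoints.
#' @param resume path of a checkpoint to resume from.
#' @return list of class `svi_config`.
#' @export
svi_config <- function(n_particles = 15, n_iterations = 80000, lr = 1e-3,
                       lr_end = 1e-4, rank = NULL, rank_warmup = 0,
                       seed = 1, grad_clip = 1e4, checkpoint = NULL,
                       checkpoint_every = 1000, resume = NULL) {
  stopifnot(n_particles >= 1, n_iterations >= 1, rank_warmup >= 0)
  structure(list(n_particles = n_particles, n_iterations = n_iterations,
                 lr = lr, lr_end = lr_end, rank = rank,
                 rank_warmup = rank_warmup, seed = seed,
                 grad_clip = grad_clip, checkpoint = checkpoint,
                 checkpoint_every = checkpoint_every, resume = resume),
            class = "svi_config")
}

#' Monte Carlo ELBO estimate
#'
#' Mean over particles of `log p(z, data) + log |J| - log q(u)` for draws
#' `u` from the guide. Particles with a non-finite model density are
#' dropped (with a warning reporting how many).
#'
#' @param guide a guide state.
#' @param model a model object (see [vp_model()]).
#' @param n_particles number of Monte Carlo particles.
#' @param seed RNG seed.
#' @return scalar ELBO estimate.
#' @export
elbo_estimate <- function(guide, model, n_particles = 15, seed = 1) {
  set.seed(seed)
  gs <- guide_sample(guide, n_particles)
  fv <- apply(gs$U, 2, model$f)
  lq <- guide_logdens(guide, gs$U)
  bad <- !is.finite(fv)
  if (any(bad)) warning(sprintf("%d non-finite particle(s) dropped", sum(bad)))
  if (all(bad)) return(-Inf)
  mean(fv[!bad] - lq[!bad])
}

#' Fit a model by stochastic variational inference
#'
#' Reparameterized stochastic gradient ascent on the ELBO with a low-rank
#' multivariate normal guide and analytic guide entropy. The ELBO trace is
#' recorded every iteration; the whole run is deterministic given
#' `config$seed`. Non-finite particles are skipped and counted; if every
#' particle of an iteration fails the fit aborts with a diagnostic naming
#' the worst-scoring window (when the model can score windows).
#'
#' @param model model object from [vp_model()] (or any list providing
#'   `D`, `f_grad`, optionally `f`, `init_loc`, `per_sample_lik`).
#' @param config an [svi_config()].
#' @return object of class `svi_fit`: guide state, per-iteration `elbo`
#'   trace, the config, particle-failure count and wall time.
#' @export
fit_svi <- function(model, config = svi_config()) {
  t0 <- proc.time()[3]
  set.seed(config$seed)
  D <- model$D
  r <- if (is.null(config$rank)) min(50L, D) else as.integer(config$rank)
  loc <- if (!is.null(model$init_loc)) as.numeric(model$init_loc) else numeric(D)
  log_d <- rep(log(0.1), D)
  W <- if (r > 0) matrix(0, D, r) else NULL
  P <- config$n_particles
  n_it <- config$n_iterations
  adam <- list(m = list(loc = 0, log_d = 0, W = 0),
               v = list(loc = 0, log_d = 0, W = 0), t = 0, tW = 0)
  it0 <- 0L
  elbo <- numeric(n_it)
  n_bad_total <- 0L
  if (!is.null(config$resume)) {
    st <- readRDS(config$resume)
    loc <- st$loc; log_d <- st$log_d; W <- st$W; adam <- st$adam
    it0 <- st$iter; elbo[seq_len(it0)] <- st$elbo[seq_len(it0)]
    n_bad_total <- st$n_bad_total
    set.seed(st$rng_seed_next)
  }
  b1 <- 0.9; b2 <- 0.999; eps_ad <- 1e-8
  upd <- function(nm, g, lr_t, tstep) {
    adam$m[[nm]] <<- b1 * adam$m[[nm]] + (1 - b1) * g
    adam$v[[nm]] <<- b2 * adam$v[[nm]] + (1 - b2) * g^2
    mh <- adam$m[[nm]] / (1 - b1^tstep)
    vh <- adam$v[[nm]] / (1 - b2^tstep)
    lr_t * mh / (sqrt(vh) + eps_ad)
  }
  dead_run <- 0L
  for (it in (it0 + 1L):n_it) {
    lr_t <- config$lr_end + (config$lr - config$lr_end) *
      0.5 * (1 + cos(pi * (it - 1) / max(n_it - 1, 1)))
    d <- exp(log_d)
    r_on <- r > 0 && it > (config$rank_warmup %||% 0)
    gloc <- numeric(D); gld <- numeric(D)
    gW <- if (r_on) matrix(0, D, r) else NULL
    facc <- 0; nok <- 0L
    u_last <- NULL
    for (p in seq_len(P)) {
      eps <- rnorm(D)
      eta <- if (r_on) rnorm(r) else NULL
      u <- loc + d * eps
      if (r_on) u <- u + drop(W %*% eta)
      fg <- model$f_grad(u)
      u_last <- u
      if (!is.finite(fg$value) || any(!is.finite(fg$grad))) {
        n_bad_total <- n_bad_total + 1L
        next
      }
      g <- fg$grad
      gloc <- gloc + g
      gld <- gld + g * eps * d
      if (r_on) gW <- gW + tcrossprod(g, eta)
      facc <- facc + fg$value
      nok <- nok + 1L
    }
    if (nok == 0L) {
      # transient fully-failed iterations are skipped; persistent failure
      # is divergence
      dead_run <- dead_run + 1L
      n_bad_total <- n_bad_total + 0L
      elbo[it] <- if (it > 1) elbo[it - 1] else NA_real_
      if (dead_run >= 20L) {
        diag_msg <- ""
        if (!is.null(model$per_sample_lik) && !is.null(u_last)) {
          psl <- model$per_sample_lik(u_last)
          diag_msg <- sprintf(" (worst-scoring window: %d, log-lik %.1f)",
                              which.min(psl), min(psl))
        }
        stop(sprintf("SVI diverged at iteration %d: all %d particles non-finite for %d iterations%s",
                     it, P, dead_run, diag_msg), call. = FALSE)
      }
      next
    }
    dead_run <- 0L
    gloc <- gloc / nok; gld <- gld / nok
    if (r_on) gW <- gW / nok
    gst <- guide_state(loc, log_d, if (r_on) W else NULL)
    eg <- .entropy_grad(gst)
    gld <- gld + eg$log_d
    if (r_on) gW <- gW + eg$W
    gn <- sqrt(sum(gloc^2) + sum(gld^2) + if (r_on) sum(gW^2) else 0)
    if (is.finite(config$grad_clip) && gn > config$grad_clip) {
      sc <- config$grad_clip / gn
      gloc <- gloc * sc; gld <- gld * sc
      if (r_on) gW <- gW * sc
    }
    adam$t <- adam$t + 1
    loc <- loc + upd("loc", gloc, lr_t, adam$t)
    log_d <- pmin(log_d + upd("log_d", gld, lr_t, adam$t), 5)
    if (r_on) {
      # the factor gets its own Adam clock, starting at its activation
      adam$tW <- adam$tW + 1
      W <- W + upd("W", gW, lr_t, adam$tW)
    }
    elbo[it] <- facc / nok + guide_entropy(guide_state(loc, log_d, W))
    if (!is.null(config$checkpoint) && it %% config$checkpoint_every == 0) {
      saveRDS(list(loc = loc, log_d = log_d, W = W, adam = adam, iter = it,
                   elbo = elbo, n_bad_total = n_bad_total,
                   rng_seed_next = sample.int(.Machine$integer.max, 1)),
              config$checkpoint)
    }
  }
  structure(list(guide = guide_state(loc, log_d, W), elbo = elbo,
                 config = config, n_bad_particles = n_bad_total,
                 wall_time = proc.time()[3] - t0,
                 nodes = model$nodes),
            class = "svi_fit")
}

#' @export
print.svi_fit <- function(x, ...) {
  cat(sprintf("<svi_fit> D = %d, rank = %d, %d iterations, final ELBO %.1f\n",
              x$guide$D, x$guide$r, length(x$elbo),
              mean(tail(x$elbo, ceiling(length(x$elbo) / 50)))))
  if (x$n_bad_particles > 0)
    cat(sprintf("  %d non-finite particle(s) skipped during training\n",
                x$n_bad_particles))
  invisible(x)
}

#' Draw from the fitted posterior approximation
#'
#' Draws from the low-rank multivariate normal guide and pushes them back
#' through the support transforms, so every draw respects the constrained
#' supports.
#'
#' @param fit an [fit_svi()] result.
#' @param n number of draws (0 gives empty draws).
#' @param seed RNG seed.
#' @return a `latent_draws` when the fit carries a node table, otherwise
#'   the unconstrained draw matrix.
#' @export
sample_posterior <- function(fit, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  U <- if (n > 0) guide_sample(fit$guide, n)$U
       else matrix(numeric(0), fit$guide$D, 0)
  if (is.null(fit$nodes)) return(U)
  z <- untransform_latents(U, fit$nodes)
  z <- matrix(z, fit$guide$D, n,
              dimnames = list(fit$nodes$table$name, NULL))
  structure(list(z = z, nodes = fit$nodes), class = "latent_draws")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
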