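#' Hierarchy layout of a cohort
#'
#' Describes the four-level structure (cohort, patient, 24h sample, event)
#' over which the latent variables are estimated: how many patients, how
#' many windows per patient, and how many meal / bolus / activity events in
#' each window.
#'
#' @param n_patients number of patients.
#' @param n_samples windows per patient (scalar or length-`n_patients`).
#' @param n_meals,n_boluses,n_exercise events per window: scalar or vector
#'   over all windows in patient-major order.
#' @return object of class `vp_hierarchy`.
#' @export
vp_hierarchy <- function(n_patients, n_samples, n_meals = 3, n_boluses = 2,
                         n_exercise = 0) {
  n_samples <- rep_len(n_samples, n_patients)
  S <- sum(n_samples)
  h <- list(n_patients = n_patients, n_samples = n_samples,
            sample_patient = rep(seq_len(n_patients), n_samples),
            n_meals = rep_len(n_meals, S),
            n_boluses = rep_len(n_boluses, S),
            n_exercise = rep_len(n_exercise, S))
  stopifnot(n_patients >= 1, all(n_samples >= 1))
  class(h) <- "vp_hierarchy"
  h
}

#' @rdname vp_hierarchy
#' @param samples list of [sample24h()] windows.
#' @param patient_ids patient identifier per window (defaults to the
#'   windows' own `patient_id` fields).
#' @export
hierarchy_from_samples <- function(samples, patient_ids = NULL) {
  if (is.null(patient_ids))
    patient_ids <- vapply(samples, function(s) as.character(s$patient_id), "")
  pid <- factor(patient_ids, levels = unique(patient_ids))
  o <- order(as.integer(pid))
  if (any(o != seq_along(samples)))
    stop("samples must be grouped by patient (patient-major order)")
  vp_hierarchy(nlevels(pid), as.integer(table(pid)),
               vapply(samples, function(s) nrow(s$meals), 0L),
               vapply(samples, function(s) nrow(s$boluses), 0L),
               vapply(samples, function(s) nrow(s$exercise), 0L))
}

# per-event slot orders shared with the engine
.meal_lat <- c("TD", "tauD2", "MA")
.bolus_lat <- c("TI", "tauI1", "IA")
.ex_lat <- c("TP", "tauP_long", "tauP_short", "P_long", "P_short")

#' Expand the prior table over a hierarchy into a node table
#'
#' Every latent becomes one node per unit of its level (one per patient,
#' one per window, one per event...), with prior locations and scales
#' resolved to either constants or references to parent / scale nodes.
#' The result also carries, per window, the map from engine parameter
#' slots to node indices.
#'
#' @param hier a [vp_hierarchy()].
#' @param priors a [vp_priors()] table.
#' @return object of class `vp_nodes`.
#' @export
build_nodes <- function(hier, priors = vp_priors()) {
  S <- length(hier$sample_patient)
  prow <- function(level) priors[priors$level == level, , drop = FALSE]
  pc <- prow("cohort"); pp <- prow("patient")
  ps <- prow("sample")
  # EGP's location references the window's SIE: create it after SIE
  ps <- ps[order(ps$loc_mode == "egp"), , drop = FALSE]
  pm <- prow("meal"); pb <- prow("bolus"); pe <- prow("exercise")
  pm <- pm[match(.meal_lat, pm$latent), , drop = FALSE]
  pb <- pb[match(.bolus_lat, pb$latent), , drop = FALSE]
  pe <- pe[match(.ex_lat, pe$latent), , drop = FALSE]

  D <- nrow(pc) + nrow(pp) * hier$n_patients + nrow(ps) * S +
    sum(hier$n_meals) * 3 + sum(hier$n_boluses) * 3 + sum(hier$n_exercise) * 5
  name <- character(D); latent <- character(D); level <- character(D)
  patient <- rep(NA_integer_, D); sampid <- rep(NA_integer_, D)
  family <- character(D); loc_mode <- character(D)
  loc_const <- rep(NA_real_, D)
  loc_a <- rep(NA_integer_, D); loc_b <- rep(NA_integer_, D)
  loc_c <- rep(NA_integer_, D)
  scale_mode <- character(D); scale_const <- rep(NA_real_, D)
  scale_id <- rep(NA_integer_, D)
  lower <- numeric(D); upper <- numeric(D); fd <- numeric(D)
  k <- 0L
  cid <- integer(0)                         # cohort node id by latent
  pid <- list(); sid <- list()              # patient / sample ids by latent

  addrow <- function(r, nm, p, s, la, lb, lc, sc_id) {
    k <<- k + 1L
    name[k] <<- nm; latent[k] <<- r$latent; level[k] <<- r$level
    patient[k] <<- p; sampid[k] <<- s
    family[k] <<- r$family; loc_mode[k] <<- r$loc_mode
    loc_const[k] <<- r$loc
    loc_a[k] <<- la; loc_b[k] <<- lb; loc_c[k] <<- lc
    scale_mode[k] <<- r$scale_mode; scale_const[k] <<- r$scale
    scale_id[k] <<- sc_id
    lower[k] <<- r$lower; upper[k] <<- r$upper; fd[k] <<- r$fd
    k
  }
  res_scale <- function(r, p) {
    if (r$scale_mode != "node") return(NA_integer_)
    nm <- r$scale_node
    if (nm %in% names(cid)) return(unname(cid[nm]))
    pid[[nm]][p]
  }

  for (i in seq_len(nrow(pc))) {
    r <- pc[i, ]
    cid[r$latent] <- addrow(r, paste0(r$latent, ".c"), NA, NA, NA, NA, NA, NA)
  }
  for (p in seq_len(hier$n_patients)) {
    for (i in seq_len(nrow(pp))) {
      r <- pp[i, ]
      la <- if (r$loc_mode == "parent") cid[[r$latent]] else NA_integer_
      id <- addrow(r, sprintf("%s.p%d", r$latent, p), p, NA, la, NA, NA,
                   res_scale(r, p))
      if (is.null(pid[[r$latent]])) pid[[r$latent]] <- integer(hier$n_patients)
      pid[[r$latent]][p] <- id
    }
  }
  for (s in seq_len(S)) {
    p <- hier$sample_patient[s]
    for (i in seq_len(nrow(ps))) {
      r <- ps[i, ]
      la <- lb <- lc <- NA_integer_
      if (r$loc_mode == "parent") la <- pid[[r$latent]][p]
      if (r$loc_mode == "egp") {
        la <- pid[["EGPi"]][p]; lb <- pid[["EGPm"]][p]; lc <- sid[["SIE"]][s]
      }
      id <- addrow(r, sprintf("%s.s%d", r$latent, s), p, s, la, lb, lc,
                   res_scale(r, p))
      if (is.null(sid[[r$latent]])) sid[[r$latent]] <- integer(S)
      sid[[r$latent]][s] <- id
    }
  }
  ev_ids <- vector("list", S)
  addev <- function(tab, tag, s, p, n_ev) {
    ids <- integer(0)
    for (e in seq_len(n_ev)) {
      for (i in seq_len(nrow(tab))) {
        r <- tab[i, ]
        la <- if (r$loc_mode == "parent") pid[[r$latent]][p] else NA_integer_
        ids <- c(ids, addrow(r, sprintf("%s.s%d.%s%d", r$latent, s, tag, e),
                             p, s, la, NA, NA, NA))
      }
    }
    ids
  }
  for (s in seq_len(S)) {
    p <- hier$sample_patient[s]
    ev_ids[[s]] <- c(addev(pm, "m", s, p, hier$n_meals[s]),
                     addev(pb, "b", s, p, hier$n_boluses[s]),
                     addev(pe, "e", s, p, hier$n_exercise[s]))
  }

  transform <- ifelse(is.finite(lower) & is.finite(upper), "logit",
                      ifelse(is.finite(lower), "log_lb", "identity"))
  tab <- data.frame(name = name, latent = latent, level = level,
                    patient = patient, sample = sampid, family = family,
                    loc_mode = loc_mode, loc_const = loc_const,
                    loc_a = loc_a, loc_b = loc_b, loc_c = loc_c,
                    scale_mode = scale_mode, scale_const = scale_const,
                    scale_id = scale_id, lower = lower, upper = upper,
                    transform = transform, fd = fd, stringsAsFactors = FALSE)
  # engine slot map: header latents then event nodes, per window
  header <- c("VG", "GEZI", "EGP", "SIE", "SIA", "SIphi", "tauG", "tauI1",
              "tauI2", "tauI3", "tauI4", "tauE", "SE", "H", "Gth", "sigma",
              "X0", "S0", "Ip0", "tauD1")
  slot_map <- vector("list", S)
  for (s in seq_len(S)) {
    p <- hier$sample_patient[s]
    hd <- vapply(header, function(l) {
      if (!is.null(sid[[l]]) && sid[[l]][s] > 0) sid[[l]][s] else pid[[l]][p]
    }, 0L)
    slot_map[[s]] <- c(hd, ev_ids[[s]])
  }
  structure(list(table = tab, slot_map = slot_map, hier = hier,
                 priors = priors, cohort_ids = cid, patient_ids = pid,
                 sample_ids = sid),
            class = "vp_nodes")
}

#' @export
print.vp_nodes <- function(x, ...) {
  cat(sprintf("<vp_nodes> %d latent nodes: %d patients, %d windows\n",
              nrow(x$table), x$hier$n_patients,
              length(x$hier$sample_patient)))
  print(table(x$table$level))
  invisible(x)
}

# resolve prior location / scale matrices for a D x K latent matrix
.resolve_loc_scale <- function(z, tab) {
  z <- as.matrix(z)
  K <- ncol(z)
  loc <- matrix(tab$loc_const, nrow(tab), K)
  ip <- which(tab$loc_mode == "parent")
  if (length(ip)) {
    lv <- z[tab$loc_a[ip], , drop = FALSE]
    # nested log-normal: the parent enters through its log
    il <- tab$family[ip] == "lnorm"
    lv[il, ] <- log(lv[il, , drop = FALSE])
    loc[ip, ] <- lv
  }
  ie <- which(tab$loc_mode == "egp")
  if (length(ie))
    loc[ie, ] <- z[tab$loc_a[ie], , drop = FALSE] +
      z[tab$loc_b[ie], , drop = FALSE] * z[tab$loc_c[ie], , drop = FALSE]
  sc <- matrix(tab$scale_const, nrow(tab), K)
  isn <- which(tab$scale_mode == "node")
  if (length(isn)) sc[isn, ] <- z[tab$scale_id[isn], , drop = FALSE]
  list(loc = loc, scale = sc)
}

#' Draw latent values from the hierarchical prior
#'
#' Draws cohort values first, then patient, window and event values
#' conditional on their parents, so cohort draws are shared across a
#' patient's windows and so on down the hierarchy. All draws respect the
#' prior supports.
#'
#' @param nodes a [build_nodes()] result.
#' @param n number of joint draws.
#' @param seed optional RNG seed.
#' @return `latent_draws`: a list with the `D x n` matrix `z` (rows follow
#'   `nodes$table`) and the node table.
#' @export
sample_latents <- function(nodes, n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- nodes$table
  D <- nrow(tab)
  z <- matrix(NA_real_, D, n)
  for (i in seq_len(D)) {
    loc <- switch(tab$loc_mode[i],
                  const = rep(tab$loc_const[i], n),
                  parent = if (tab$family[i] == "lnorm") log(z[tab$loc_a[i], ])
                           else z[tab$loc_a[i], ],
                  egp = z[tab$loc_a[i], ] + z[tab$loc_b[i], ] * z[tab$loc_c[i], ])
    sc <- if (tab$scale_mode[i] == "node") z[tab$scale_id[i], ]
          else rep(tab$scale_const[i], n)
    z[i, ] <- switch(tab$family[i],
      tnorm = rtnorm(n, loc, sc, tab$lower[i], tab$upper[i]),
      norm = rnorm(n, loc, sc),
      lnorm = exp(rnorm(n, loc, sc)),
      unif = runif(n, tab$lower[i], tab$upper[i]),
      expo = rexp(n, rate = 1 / loc),
      halfnorm = abs(rnorm(n, 0, sc)),
      stop("unknown family"))
  }
  rownames(z) <- tab$name
  structure(list(z = z, nodes = nodes), class = "latent_draws")
}

#' Draw a window's endogenous glucose production given its insulin
#' sensitivity
#'
#' The EGP-SI linkage: `EGP ~ TN(EGPi + EGPm * SIE, sigma_EGP)` truncated
#' below at zero, so the correlation between a patient's per-window EGP and
#' SI values carries the sign of `EGPm`.
#'
#' @param EGPi patient intercept (mg/dL/min), >= 0.
#' @param EGPm patient slope.
#' @param SIE window insulin sensitivity.
#' @param sigma_EGP spread (>= 0; 0 gives the degenerate point mass).
#' @param n number of draws.
#' @return numeric vector of EGP draws.
#' @export
egp_for_sample <- function(EGPi, EGPm, SIE, sigma_EGP, n = 1) {
  if (EGPi < 0) stop("EGPi must be non-negative")
  if (sigma_EGP < 0) stop("sigma_EGP must be non-negative")
  m <- EGPi + EGPm * SIE
  if (sigma_EGP == 0) return(rep(max(m, 0), n))
  rtnorm(n, m, sigma_EGP, 0, Inf)
}

# prior log-density of a D x K matrix of constrained values, per column
log_prior <- function(z, nodes) {
  z <- as.matrix(z)
  tab <- nodes$table
  ls <- .resolve_loc_scale(z, tab)
  lp <- matrix(0, nrow(tab), ncol(z))
  for (fam in unique(tab$family)) {
    i <- which(tab$family == fam)
    x <- z[i, , drop = FALSE]
    m <- ls$loc[i, , drop = FALSE]; s <- ls$scale[i, , drop = FALSE]
    l <- tab$lower[i]; u <- tab$upper[i]
    lp[i, ] <- switch(fam,
      tnorm = dtnorm(x, m, s, l, u),
      norm = dnorm(x, m, s, log = TRUE),
      lnorm = ifelse(x > 0, dnorm(log(x), m, s, log = TRUE) - log(x), -Inf),
      unif = ifelse(x >= l & x <= u, -log(u - l), -Inf),
      expo = ifelse(x >= 0, -x / m - log(m), -Inf),
      halfnorm = ifelse(x >= 0, log(2) + dnorm(x, 0, s, log = TRUE), -Inf))
  }
  colSums(lp)
}

# engine-facing data for each window
prepare_engine_data <- function(samples) lapply(samples, as_engine_data)

#' Joint log-density of latents and data
#'
#' Sum of all prior log-densities (with truncation normalizers) and the
#' CGM likelihood: independent `Normal(CGM | SG(t), sigma_window)` terms
#' with the simulated subcutaneous glucose interpolated to the CGM
#' timestamps. Out-of-support latents give `-Inf` rather than an error.
#'
#' @param z constrained latent vector (rows of `nodes$table`).
#' @param nodes a [build_nodes()] result.
#' @param samples list of [sample24h()] windows (order matching the
#'   hierarchy), or the result of a previous `prepare_engine_data()`.
#' @param grid_dt simulation grid step (min).
#' @return scalar log density.
#' @export
log_joint <- function(z, nodes, samples, grid_dt = 1) {
  lp <- log_prior(z, nodes)
  if (!is.finite(lp)) return(-Inf)
  ed <- if (inherits(samples[[1]], "sample24h")) prepare_engine_data(samples)
        else samples
  slots <- lapply(nodes$slot_map, function(m) z[m])
  lp + cpp_loglik_batch(slots, ed, grid_dt)
}

#' Assemble one window's simulator parameters from latent draws
#'
#' Deterministically flattens the hierarchy for a given window: every
#' simulator parameter is traced to exactly one latent node (patient-level
#' nodes shared across the patient's windows, event-level nodes private to
#' their event). The inverse, `scatter_sample_params()`, writes a slot
#' vector back into a latent vector.
#'
#' @param latents a `latent_draws` (first column used) or latent vector.
#' @param nodes a [build_nodes()] result.
#' @param sample_idx global window index.
#' @return list with `params` (a [sim_params()]), and per-event modifier
#'   data.frames `meals`, `boluses`, `exercise`.
#' @export
assemble_sample_params <- function(latents, nodes, sample_idx) {
  z <- if (inherits(latents, "latent_draws")) latents$z[, 1] else latents
  map <- nodes$slot_map[[sample_idx]]
  v <- z[map]
  h <- setNames(v[1:20], .slot_header)
  p <- sim_params(VG = h[["VG"]], GEZI = h[["GEZI"]], EGP = h[["EGP"]],
                  SIE = h[["SIE"]], SIA = h[["SIA"]], SIphi = h[["SIphi"]],
                  tauG = h[["tauG"]], tauI1 = h[["tauI1"]],
                  tauI2 = h[["tauI2"]], tauI3 = h[["tauI3"]],
                  tauI4 = h[["tauI4"]], tauD1 = h[["tauD1"]],
                  tauE = h[["tauE"]], SE = h[["SE"]], H = h[["H"]],
                  Gth = h[["Gth"]], sigma = h[["sigma"]], X0 = h[["X0"]],
                  S0 = h[["S0"]], Ip0 = h[["Ip0"]])
  hier <- nodes$hier
  nm <- hier$n_meals[sample_idx]; nb <- hier$n_boluses[sample_idx]
  ne <- hier$n_exercise[sample_idx]
  em <- v[-(1:20)]
  meals <- boluses <- exercise <- NULL
  if (nm > 0) {
    m <- matrix(em[seq_len(3 * nm)], ncol = 3, byrow = TRUE)
    meals <- data.frame(TD = m[, 1], tauD2 = m[, 2], MA = m[, 3])
  }
  if (nb > 0) {
    m <- matrix(em[3 * nm + seq_len(3 * nb)], ncol = 3, byrow = TRUE)
    boluses <- data.frame(TI = m[, 1], tauI1 = m[, 2], IA = m[, 3])
  }
  if (ne > 0) {
    m <- matrix(em[3 * nm + 3 * nb + seq_len(5 * ne)], ncol = 5, byrow = TRUE)
    exercise <- data.frame(TP = m[, 1], tauP_long = m[, 2],
                           tauP_short = m[, 3], P_long = m[, 4],
                           P_short = m[, 5])
  }
  list(params = p, meals = meals, boluses = boluses, exercise = exercise)
}

#' @rdname assemble_sample_params
#' @param slot_values list (over windows) of slot vectors.
#' @export
scatter_sample_params <- function(slot_values, nodes) {
  z <- rep(NA_real_, nrow(nodes$table))
  for (s in seq_along(slot_values)) z[nodes$slot_map[[s]]] <- slot_values[[s]]
  names(z) <- nodes$table$name
  z
}

# decorate a sample24h's event tables with a draw's event-level modifiers
decorate_sample <- function(s, asm) {
  if (!is.null(asm$meals)) s$meals <- cbind(s$meals[, c("t", "carbs", "fat", "protein")], asm$meals)
  if (!is.null(asm$boluses)) s$boluses <- cbind(s$boluses[, c("t", "dose")], asm$boluses)
  if (!is.null(asm$exercise)) s$exercise <- cbind(s$exercise[, "t", drop = FALSE], asm$exercise)
  s
}

# simulate window s under latent vector z (engine-level, no validation)
simulate_from_latents <- function(z, nodes, engine_data, s_idx, grid_dt = 1,
                                  backend = "analytic_forcing", ode_dt = 0.25) {
  cpp_simulate(z[nodes$slot_map[[s_idx]]], engine_data[[s_idx]], grid_dt,
               backend, ode_dt)
}

#' Prior-predictive simulation for one exemplary day
#'
#' Draws `n` full latent vectors from the prior for a single-window
#' hierarchy matching the supplied day's events, simulates each, and
#' summarizes whether the implied glucose trajectories stay inside the
#' physiological 0-400 mg/dL band. With `condition = "zero_insulin"` all
#' insulin (boluses, basal, initial insulin state) and meals are removed,
#' the regime where glucose should climb towards the renally-limited
#' equilibrium near 400 mg/dL.
#'
#' @param sample a [sample24h()] exemplary day.
#' @param priors a [vp_priors()] table.
#' @param n ensemble size.
#' @param seed RNG seed.
#' @param condition `"none"` or `"zero_insulin"`.
#' @param grid_dt simulation step (min).
#' @return list with `SG` (matrix, `n` columns), `t`, `frac_in_range`
#'   (fraction of trajectory-minutes inside \[0, 400\] mg/dL), and
#'   `terminal` (end-of-window glucose per draw; trajectories that left the
#'   integrable range count as out-of-range for the remainder and get an
#'   `NA` terminal value).
#' @export
prior_predictive <- function(sample, priors = vp_priors(), n = 100,
                             seed = NULL, condition = c("none", "zero_insulin"),
                             grid_dt = 2) {
  condition <- match.arg(condition)
  stopifnot(n >= 1)
  if (condition == "zero_insulin") {
    sample$boluses <- sample$boluses[0, , drop = FALSE]
    sample$meals <- sample$meals[0, , drop = FALSE]
    sample$basal <- 0
  }
  hier <- hierarchy_from_samples(list(sample), "p1")
  nodes <- build_nodes(hier, priors)
  draws <- sample_latents(nodes, n, seed)
  if (condition == "zero_insulin") {
    i0 <- nodes$table$latent %in% c("X0", "S0", "Ip0")
    draws$z[i0, ] <- 0
  }
  ed <- prepare_engine_data(list(sample))
  nt <- as.integer(round(sample$t_end / grid_dt)) + 1L
  SG <- matrix(NA_real_, nt, n)
  term <- rep(NA_real_, n)
  n_in <- 0; n_tot <- 0
  for (j in seq_len(n)) {
    o <- simulate_from_latents(draws$z[, j], nodes, ed, 1, grid_dt)
    m <- length(o$SG)
    SG[seq_len(m), j] <- o$SG
    n_in <- n_in + sum(o$SG >= 0 & o$SG <= 400)
    n_tot <- n_tot + nt
    if (o$ok) term[j] <- o$G[m]
  }
  list(t = seq(0, sample$t_end, by = grid_dt), SG = SG,
       frac_in_range = n_in / n_tot, terminal = term, draws = draws)
}
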