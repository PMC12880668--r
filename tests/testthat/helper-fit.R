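# Shared fitted objects, built lazily once per test run. The mini fit is
# deliberately small (2 patients x 2 windows, few hundred iterations): it
# is used where tests need *a* fitted object, not a converged one. The
# recovery fit (2 x 4 windows, 2000 iterations) backs the acceptance
# checks and is cached for reuse across criteria.

.fit_cache <- new.env(parent = emptyenv())

get_mini_cohort <- function() {
  if (is.null(.fit_cache$mini_coh))
    .fit_cache$mini_coh <- generate_cohort(
      cohort_config(n_patients = 2, samples_per_patient = 2, seed = 7))
  .fit_cache$mini_coh
}

get_mini_fit <- function() {
  if (is.null(.fit_cache$mini_fit)) {
    coh <- get_mini_cohort()
    m <- vp_model(coh$samples, nodes = coh$nodes, grid_dt = 5)
    .fit_cache$mini_fit <- fit_svi(
      m, svi_config(n_particles = 2, n_iterations = 250, rank = 5, seed = 2,
                    lr = 0.02, lr_end = 0.002))
  }
  .fit_cache$mini_fit
}

get_recovery_cohort <- function() {
  if (is.null(.fit_cache$rec_coh))
    .fit_cache$rec_coh <- generate_cohort(
      cohort_config(n_patients = 2, samples_per_patient = 4, seed = 11))
  .fit_cache$rec_coh
}

get_recovery_fit <- function() {
  if (is.null(.fit_cache$rec_fit)) {
    coh <- get_recovery_cohort()
    m <- vp_model(coh$samples, nodes = coh$nodes, grid_dt = 5)
    .fit_cache$rec_fit <- fit_svi(
      m, svi_config(n_particles = 4, n_iterations = 2000, rank = 20,
                    rank_warmup = 600, seed = 3, lr = 0.02, lr_end = 0.002))
  }
  .fit_cache$rec_fit
}
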