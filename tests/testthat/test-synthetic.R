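# Synthetic-cohort generator: reproducibility, event-density calibration,
# noise calibration, filter compatibility and defect injection.

test_that("generation is seed-reproducible and respects prior supports", {
  cfg <- cohort_config(n_patients = 2, samples_per_patient = 2, seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$truth$z, b$truth$z)
  for (s in seq_along(a$samples))
    expect_identical(a$samples[[s]]$cgm$glucose, b$samples[[s]]$cgm$glucose)
  expect_identical(a$records$P01$events$value, b$records$P01$events$value)
  tab <- a$nodes$table
  expect_true(all(a$truth$z >= tab$lower & a$truth$z <= tab$upper))
})

test_that("event densities emulate the free-living cohort composition", {
  # ~2.7 meals, ~1.9 boluses, ~0.33 activities per window on average
  cfg <- cohort_config(n_patients = 4, samples_per_patient = 40, seed = 21)
  set.seed(21)
  n <- 4 * 40
  sch <- replicate(n, glucopop:::.schedule_day(cfg), simplify = FALSE)
  nm <- vapply(sch, function(s) nrow(s$meals), 0L)
  nb <- vapply(sch, function(s) nrow(s$boluses), 0L)
  ne <- vapply(sch, function(s) nrow(s$exercise), 0L)
  expect_lt(abs(mean(nm) - 2.7), 0.25)
  expect_lt(abs(mean(nb) - 1.86), 0.3)
  expect_lt(abs(mean(ne) - 0.33), 0.15)
  expect_true(all(nm >= 2) && all(nb >= 1))
})

test_that("CGM noise matches the window's sigma and windows pass the filters", {
  cfg <- cohort_config(n_patients = 2, samples_per_patient = 3, seed = 5)
  coh <- generate_cohort(cfg)
  nodes <- coh$nodes
  ed <- glucopop:::prepare_engine_data(coh$samples)
  resid_sd <- sig_true <- numeric(length(coh$samples))
  for (s in seq_along(coh$samples)) {
    o <- glucopop:::simulate_from_latents(coh$truth$z, nodes, ed, s, 5)
    sg <- o$SG[1 + coh$samples[[s]]$cgm$t / 5]
    r <- coh$samples[[s]]$cgm$glucose - sg
    resid_sd[s] <- sd(r[-1]) # first reading is pinned to the initial value
    sig_true[s] <- coh$truth$z[nodes$slot_map[[s]][16]]
  }
  # pooled over windows the noise scale is right (AR(1) noise makes the
  # per-window estimator wide, so compare in aggregate)
  expect_lt(abs(mean(resid_sd / sig_true) - 1), 0.10)
  # every clean window passes the five filters by construction
  out <- process_records(coh$records, min_stride = 1440)
  expect_equal(length(out$samples), 6)
  expect_true(all(out$report$pass))
})

test_that("defect injection trips exactly the designed filters", {
  cfg <- cohort_config(n_patients = 1, samples_per_patient = 6, seed = 13)
  coh <- generate_cohort(cfg)
  spec <- data.frame(patient_id = "P01", window = c(2, 3, 4, 5, 6),
                     type = c("gap", "jump", "no_meals", "no_bolus", "no_hr"))
  inj <- inject_defects(coh$records, spec)
  expect_equal(inj$manifest$fails_rule, 1:5)
  out <- process_records(inj$records, min_stride = 1440)
  rep <- out$report
  expect_equal(nrow(rep), 6)
  expect_true(rep$pass[1])
  expect_false(any(rep$pass[2:6]))
  expect_false(rep$rule1_gap[2]); expect_false(rep$rule2_jump[3])
  expect_false(rep$rule3_meals[4]); expect_false(rep$rule4_bolus[5])
  expect_false(rep$rule5_hr[6])
  # surviving-window count equals the designed count exactly
  expect_equal(length(out$samples), coh$manifest$designed_pass - nrow(spec))
  expect_error(inject_defects(coh$records,
                              data.frame(patient_id = "P01", window = 99,
                                         type = "gap")), "span")
})
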