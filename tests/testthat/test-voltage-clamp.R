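# Peak I-V, permeability-based activation curves, ramp analysis, patch QC.

test_that("zero-current recording gives zero densities", {
  rec <- simulate_ina_step_family(channel_truth(p_max = 0), noise_sd = 0)
  iv <- peak_iv(rec, reference_voltage = -25)
  expect_true(all(iv$iv$density == 0))
})

test_that("reference voltage must exist in the protocol", {
  rec <- simulate_ina_step_family(channel_truth(), steps = seq(-120, 30, 10),
                                  noise_sd = 0)
  expect_error(peak_iv(rec, reference_voltage = -25), "-25")
  iv <- peak_iv(rec, reference_voltage = -20)
  expect_lt(iv$reference_density, 0)       # inward at -20 mV
})

test_that("scaled permeability scales densities but not the activation fit", {
  t1 <- channel_truth(p_max = 1.2e-4)
  t2 <- channel_truth(p_max = 1.2e-4 * 0.65)
  r1 <- simulate_ina_step_family(t1, noise_sd = 0)
  r2 <- simulate_ina_step_family(t2, noise_sd = 0)
  iv1 <- peak_iv(r1, reference_voltage = -25)
  iv2 <- peak_iv(r2, reference_voltage = -25)
  expect_equal(iv2$reference_density / iv1$reference_density, 0.65,
               tolerance = 0.02)
  ctx <- truth_context(t1)
  a1 <- activation_curve(iv1, ctx)
  a2 <- activation_curve(iv2, ctx)
  expect_equal(a1$fit$v_half, a2$fit$v_half, tolerance = 1e-6)
  expect_equal(a1$fit$k, a2$fit$k, tolerance = 1e-6)
  # and the fit recovers the generator's gating truth
  expect_equal(a1$fit$v_half, -35.45, tolerance = 0.1)
  expect_equal(a1$fit$k, 6.47, tolerance = 0.1)
})

test_that("availability analysis recovers the inactivation truth", {
  truth <- channel_truth()
  rec <- simulate_ina_availability(truth, noise_sd = 0)
  av <- availability_curve(rec)
  expect_equal(av$fit$v_half, -58.56, tolerance = 0.05)
  expect_equal(av$fit$k, 5.30, tolerance = 0.05)
  zero <- rec
  zero$sweeps <- lapply(zero$sweeps, function(s) { s$samples[] <- 0; s })
  expect_error(availability_curve(zero), "cannot normalize")
})

test_that("ramp analysis matches the closed form and survives transients", {
  truth <- channel_truth(p_max = 6e-5, persistent_fraction = 0.01)
  clean <- simulate_ramp(truth, seed = 5, noise_sd = 0.02, capacitance = 20)
  rr <- analyze_ramp(clean, capacitance = 20, ctx = truth_context(truth))
  gt <- attr(clean, "ground_truth")
  expect_lt(abs(rr$density_at_m20 - gt$density_at_m20) / abs(gt$density_at_m20),
            0.05)
  expect_equal(rr$activation_fit$v_half, truth$act_vhalf, tolerance = 0.5)
  # injected transients are excised: result within 1% of the clean trace
  dirty <- simulate_ramp(truth, seed = 5, noise_sd = 0.02, capacitance = 20,
                         n_transients = 3)
  rr2 <- analyze_ramp(dirty, capacitance = 20)
  expect_gt(sum(rr2$n_excised), 0)
  expect_lt(abs(rr2$density_at_m20 - rr$density_at_m20) /
              abs(rr$density_at_m20), 0.01)
  # zero persistent fraction: density below the noise floor
  null <- simulate_ramp(channel_truth(persistent_fraction = 0), seed = 6,
                        noise_sd = 0.05, capacitance = 20)
  rr3 <- analyze_ramp(null, capacitance = 20)
  expect_lt(abs(rr3$density_at_m20), 3 * 0.05)
})

test_that("unusable ramps (huge transient span) are refused", {
  truth <- channel_truth(persistent_fraction = 0.01)
  tr <- simulate_ramp(truth, seed = 7, noise_sd = 0.01, capacitance = 20,
                      n_trials = 1)
  # bury 30% of the trace in one long artificial transient
  n <- length(tr[[1]]$samples)
  tr[[1]]$samples[seq(0.3 * n, 0.6 * n)] <-
    tr[[1]]$samples[seq(0.3 * n, 0.6 * n)] +
    50 * sin(seq(0, 400 * pi, length.out = length(seq(0.3 * n, 0.6 * n))))
  expect_error(analyze_ramp(tr, capacitance = 20), "unusable")
})

test_that("nucleated-patch QC applies both resistance cutoffs", {
  base <- simulate_ina_step_family(channel_truth(), noise_sd = 0,
                                   steps = c(-120, -20))
  base$access_resistance <- 15; base$input_resistance <- 2000
  expect_true(nucleated_patch_qc(base)$pass)
  ra <- base; ra$access_resistance <- 21
  expect_false(nucleated_patch_qc(ra)$pass)
  expect_match(nucleated_patch_qc(ra)$reason, "Ra")
  rin <- base; rin$input_resistance <- 500    # 0.5 GOhm
  expect_false(nucleated_patch_qc(rin)$pass)
  expect_match(nucleated_patch_qc(rin)$reason, "Rin")
  bad <- base; bad$input_resistance <- NA_real_
  expect_error(nucleated_patch_qc(bad), "present")
})
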