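# Voltage-clamp, ramp, sIPSC, and survival generators.

test_that("zero maximal permeability gives identically zero sweeps", {
  truth <- channel_truth(p_max = 0)
  rec <- simulate_ina_step_family(truth, noise_sd = 0)
  for (s in rec$sweeps) expect_true(all(s$samples == 0))
})

test_that("noiseless peak currents match the kinetic-integration oracle", {
  truth <- channel_truth(p_max = 1.2e-4)
  rec <- simulate_ina_step_family(truth, noise_sd = 0)
  iv <- peak_iv(rec, reference_voltage = -25)
  for (v in c(-60, -40, -25, -10, 0, 10)) {
    oracle <- kinetic_peak_oracle(truth, v)
    got <- iv$iv$density[iv$iv$voltage == v]
    expect_lt(abs(got - oracle) / abs(oracle), 0.005)
  }
})

test_that("steps outside the protocol range are rejected", {
  expect_error(simulate_ina_step_family(channel_truth(), steps = c(-150, 0)),
               "\\[-120, \\+60\\]")
})

test_that("hyperpolarized prepulse gives full availability", {
  truth <- channel_truth()
  rec <- simulate_ina_availability(truth, noise_sd = 0)
  av <- availability_curve(rec)
  expect_equal(av$curve$normalized[av$curve$prepulse == -120], 1,
               tolerance = 0.01)
  expect_true(all(diff(av$curve$normalized) <= 1e-9))  # monotone decreasing
})

test_that("ramp trials carry a retrievable closed-form persistent density", {
  truth <- channel_truth(p_max = 6e-5, persistent_fraction = 0.01)
  tr <- simulate_ramp(truth, seed = 2, noise_sd = 0)
  gt <- attr(tr, "ground_truth")
  ctx <- truth_context(truth)
  closed <- 0.01 * 6e-5 * ghk_current(1, -20, ctx) /
    (1 + exp((truth$act_vhalf + 20) / truth$act_k))
  expect_equal(gt$density_at_m20, closed, tolerance = 1e-12)
  # zero persistent fraction: everything within 3x noise
  tr0 <- simulate_ramp(channel_truth(persistent_fraction = 0),
                       seed = 2, noise_sd = 0.05, capacitance = 20)
  expect_lt(max(abs(tr0[[1]]$samples / 20)), 3 * 0.05 * 1.5)
  # averaging shrinks variance
  tr4 <- simulate_ramp(channel_truth(persistent_fraction = 0), n_trials = 4,
                       seed = 3, noise_sd = 0.05, capacitance = 20)
  avg <- Reduce(`+`, lapply(tr4, function(s) s$samples)) / 4
  expect_lt(var(avg), var(tr4[[1]]$samples))
  expect_error(simulate_ramp(truth, seed = 1, ramp_to = 40), "inconsistent")
})

test_that("sIPSC event generator follows its Poisson ground truth", {
  expect_equal(nrow(simulate_sipsc_events(
    synaptic_truth(rate = 0, duration = 60), seed = 1)), 0)
  counts <- vapply(1:50, function(s)
    nrow(simulate_sipsc_events(synaptic_truth(rate = 3.8, duration = 300),
                               seed = s)), integer(1))
  lambda <- 3.8 * 300
  expect_lt(abs(mean(counts) - lambda), 3 * sqrt(lambda / 50))
  ev <- simulate_sipsc_events(synaptic_truth(rate = 2, amp_mean = 35,
                                             amp_sd = 0, duration = 30),
                              seed = 4)
  expect_true(all(ev$amplitude == 35))
  expect_true(all(diff(ev$onset) > 0))
  expect_error(synaptic_truth(rise = 5, decay = 2), "decay > rise")
})

test_that("survival generator respects degenerate and censored cases", {
  h <- numeric(30); h[18] <- 1        # everyone dies on day 18
  recs <- simulate_survival(list(g = list(hazard = h, n = 12)), seed = 1)
  expect_true(all(recs$day == 18 & recs$event == 1))
  expect_equal(km_estimate(recs)$median, 18)
  # zero hazard: all censored, median undefined
  recs0 <- simulate_survival(list(g = list(hazard = numeric(90), n = 10)),
                             seed = 1, censor_day = 90)
  expect_true(all(recs0$event == 0))
  expect_true(is.na(km_estimate(recs0)$median))
  expect_error(simulate_survival(list(g = list(hazard = c(-0.1), n = 2)),
                                 seed = 1), "probabilities")
  # hazard profile targets its median
  h25 <- hazard_profile(25)
  big <- simulate_survival(list(g = list(hazard = h25, n = 4000)), seed = 2)
  expect_lt(abs(km_estimate(big)$median - 25), 1.5)
})
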