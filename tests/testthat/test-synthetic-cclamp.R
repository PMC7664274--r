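# Current-clamp simulator: protocol handling, determinism, integration
# accuracy, and the behaviors the presets are calibrated to show.

test_that("0 pA step leaves the FS cell at rest with no spikes", {
  rec <- simulate_current_clamp(neuron_preset("FS"), steps = 0, seed = 1,
                                noise_sd = 0)
  v <- rec$sweeps[[1]]$samples
  expect_true(all(v < 0))
  rmp <- mean(v[1:2000])
  expect_lt(abs(rmp - v[length(v)]), 2)   # stationary over the whole sweep
})

test_that("identical seeds give bit-identical recordings", {
  a <- simulate_current_clamp(neuron_preset("FS"), steps = c(0, 10, 20),
                              seed = 9, baseline = 0.05,
                              step_duration = 0.1, tail = 0.01)
  b <- simulate_current_clamp(neuron_preset("FS"), steps = c(0, 10, 20),
                              seed = 9, baseline = 0.05,
                              step_duration = 0.1, tail = 0.01)
  for (i in 1:3) expect_identical(a$sweeps[[i]]$samples, b$sweeps[[i]]$samples)
})

test_that("halving the integration step does not change spike counts", {
  p <- neuron_preset("FS")
  for (amp in c(100, 250)) {
    a <- simulate_current_clamp(p, steps = amp, seed = 1, noise_sd = 0,
                                baseline = 0.1, tail = 0.02, dt = 0.01)
    b <- simulate_current_clamp(p, steps = amp, seed = 1, noise_sd = 0,
                                baseline = 0.1, tail = 0.02, dt = 0.005)
    expect_equal(nrow(detect_aps(a$sweeps[[1]])),
                 nrow(detect_aps(b$sweeps[[1]])))
  }
})

test_that("sodium-conductance scaling lowers spike output monotonically", {
  p1 <- neuron_preset("FS", g_scale = 1)
  p2 <- neuron_preset("FS", g_scale = 0.65)
  r1 <- simulate_current_clamp(p1, steps = 300, seed = 1, noise_sd = 0,
                               baseline = 0.1, tail = 0.02)
  r2 <- simulate_current_clamp(p2, steps = 300, seed = 1, noise_sd = 0,
                               baseline = 0.1, tail = 0.02)
  expect_lt(nrow(detect_aps(r2$sweeps[[1]])), nrow(detect_aps(r1$sweeps[[1]])))
})

test_that("spike count is monotone in current up to the block regime", {
  rec <- simulate_current_clamp(neuron_preset("FS"), seed = 3, noise_sd = 0,
                                baseline = 0.1, tail = 0.02)
  counts <- vapply(rec$sweeps, function(s) nrow(detect_aps(s)), integer(1))
  amps <- vapply(rec$sweeps, function(s) s$command$amplitude, numeric(1))
  pos <- counts[amps >= 0]
  # allow a terminal decline (depolarization block); monotone before it
  peak_at <- which.max(pos)
  expect_true(all(diff(pos[seq_len(peak_at)]) >= 0))
})

test_that("layer-6 preset reaches depolarization block at 200 pA", {
  rec <- simulate_current_clamp(neuron_preset("RS-layer6"),
                                steps = seq(-20, 200, 10), seed = 4,
                                noise_sd = 0, baseline = 0.1, tail = 0.02)
  failures <- vapply(rec$sweeps, function(s)
    nrow(attr(detect_aps(s), "failures")), integer(1))
  expect_gt(max(failures), 0)
  counts <- vapply(rec$sweeps, function(s) nrow(detect_aps(s)), integer(1))
  expect_lt(counts[length(counts)], max(counts))   # count collapses at top
})

test_that("invalid simulator arguments are rejected", {
  expect_error(simulate_current_clamp(neuron_preset("FS"), seed = 1,
                                      sampling_rate = 5000), "20 kHz")
  expect_error(simulate_current_clamp(neuron_preset("FS"), seed = 1,
                                      dt = 0.02), "0.01")
  expect_error(neuron_preset("FS", g_scale = 1.5), "g_scale")
  expect_error(neuron_preset("FS", g_na = -1), "conductances")
})

test_that("FS features sit in the fast-spiking calibration bands", {
  rec <- simulate_current_clamp(neuron_preset("FS"), seed = 5, noise_sd = 0,
                                baseline = 0.1, tail = 0.02)
  amps <- vapply(rec$sweeps, function(s) s$command$amplitude, numeric(1))
  counts <- vapply(rec$sweeps, function(s) nrow(detect_aps(s)), integer(1))
  # analysis sweep: 20 pA above the repetitive-firing threshold
  rep_amp <- amps[which(counts > 3 & amps > 0)[1]]
  i <- which(amps == rep_amp + 20)
  fe <- ap_features(rec$sweeps[[i]], detect_aps(rec$sweeps[[i]]))
  expect_gt(mean(fe$half_width, na.rm = TRUE), 0.5)
  expect_lt(mean(fe$half_width, na.rm = TRUE), 1.2)
  expect_lt(mean(fe$ahp, na.rm = TRUE), -10)       # deep AHP
  expect_gt(mean(fe$ahp, na.rm = TRUE), -30)
})
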