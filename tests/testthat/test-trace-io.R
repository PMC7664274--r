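random_recording <- function(seed) {
  set.seed(seed)
  n_sweeps <- sample(2:5, 1)
  sr <- 20000
  sweeps <- lapply(seq_len(n_sweeps), function(i) {
    sweep_trace(rnorm(200, -70, 5), sr, channel = "voltage",
                command = list(type = "step", amplitude = -20 + 10 * i,
                               onset = 0.002, duration = 0.005, unit = "pA"),
                index = i)
  })
  episodic_recording(sweeps,
                     protocol = list(mode = "current_step", step_increment = 10),
                     cell_id = sprintf("cell%03d", seed), group = "wt",
                     junction_potential = 14.3, corrected = FALSE,
                     capacitance = runif(1, 5, 60),
                     access_resistance = runif(1, 5, 15))
}

test_that("native write/read round trip is lossless (samples bit-equal)", {
  for (seed in 1:20) {
    rec <- random_recording(seed)
    d <- file.path(tempdir(), paste0("rt", seed))
    write_recording(rec, d)
    back <- read_recording(d)
    for (i in seq_along(rec$sweeps)) {
      expect_identical(back$sweeps[[i]]$samples, rec$sweeps[[i]]$samples)
      expect_equal(back$sweeps[[i]]$command, rec$sweeps[[i]]$command)
    }
    expect_equal(back$capacitance, rec$capacitance)
    expect_equal(back$junction_potential, rec$junction_potential)
    expect_identical(back$corrected, rec$corrected)
    expect_identical(back$cell_id, rec$cell_id)
    unlink(d, recursive = TRUE)
  }
})

test_that("missing sidecar and ABF paths raise named errors", {
  d <- file.path(tempdir(), "nosidecar")
  dir.create(d, showWarnings = FALSE)
  expect_error(read_recording(d), "recording.json")
  expect_error(read_recording("trace.abf"), "ABF")
  expect_error(read_recording(d, format = "abf"), "ABF")
  rec <- random_recording(1)
  expect_error(write_recording(rec, tempdir(), format = "abf"), "ABF")
})

test_that("simulated FS family writes 33 sweeps with 10 pA increments", {
  rec <- simulate_current_clamp(neuron_preset("FS"), seed = 2, noise_sd = 0.1,
                                baseline = 0.05, step_duration = 0.05,
                                tail = 0.01)
  expect_length(rec$sweeps, 33)
  amps <- vapply(rec$sweeps, function(s) s$command$amplitude, numeric(1))
  expect_equal(unique(diff(amps)), 10)
  d <- file.path(tempdir(), "fsfam")
  write_recording(rec, d)
  back <- read_recording(d)
  expect_length(back$sweeps, 33)
  expect_equal(back$protocol$step_increment, 10)
  unlink(d, recursive = TRUE)
})

test_that("junction correction shifts voltages once and only once", {
  sw <- sweep_trace(c(-80, -70, -60), 20000, channel = "voltage",
                    command = list(type = "gapfree"))
  rec <- episodic_recording(list(sw), protocol = list(mode = "gapfree"),
                            junction_potential = 14.3, corrected = FALSE)
  cor <- apply_junction_correction(rec)
  expect_equal(cor$sweeps[[1]]$samples[1], -94.3)
  expect_true(cor$corrected)
  expect_error(apply_junction_correction(cor), "already corrected")
  # zero correction is the identity
  rec0 <- episodic_recording(list(sw), protocol = list(mode = "gapfree"),
                             junction_potential = 0, corrected = FALSE)
  cor0 <- apply_junction_correction(rec0)
  expect_equal(cor0$sweeps[[1]]$samples, sw$samples)
})

test_that("sweep and recording validation rejects malformed inputs", {
  expect_error(sweep_trace(c(1, NA), 20000), "finite")
  expect_error(sweep_trace(1:10, -5), "sampling_rate")
  expect_error(sweep_trace(1:10, 1000, command = list(type = "step",
                                                      amplitude = 10,
                                                      onset = 0, duration = 1)),
               "past the end")
  s1 <- sweep_trace(rnorm(10), 20000, channel = "voltage")
  s2 <- sweep_trace(rnorm(10), 10000, channel = "voltage")
  expect_error(episodic_recording(list(s1, s2)), "sampling rate")
})
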