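# Current-clamp step-family simulator.

#' Simulate a current-clamp step family
#'
#' Integrates the single-compartment conductance model of a
#' [neuron_preset()] through a family of 1-s current steps (10 pA
#' increments by default, matching the acquisition protocol the study
#' presets emulate: -20 to 300 pA for FS interneurons, -20 to 200 pA for
#' pyramidal cells), and packages the voltage traces as an episodic
#' recording with known ground truth. Gaussian noise is added to the
#' recorded signal only; the integration itself is deterministic.
#'
#' @param preset A [neuron_preset()].
#' @param steps Step amplitudes (pA). Default -20 to 300 pA for the FS
#'   preset and -20 to 200 pA otherwise, in 10 pA increments.
#' @param noise_sd Recording noise SD (mV), added to the sampled trace.
#' @param seed RNG seed (required; determinism contract).
#' @param sampling_rate Samples per second, >= 20000.
#' @param baseline,step_duration,tail Segment durations (s): zero-current
#'   baseline before the step, the step itself, and the post-step tail.
#' @param dt Integration step (ms), <= 0.01 and an exact divisor of the
#'   sampling interval.
#' @param ljp If nonzero, the emitted traces are shifted by +ljp to emulate
#'   uncorrected raw recordings (correct with
#'   [apply_junction_correction()]); if 0 the recording is already in
#'   corrected space.
#' @param cell_id,group Identity metadata passed into the recording.
#' @return A [episodic_recording()] (voltage channel, protocol
#'   `current_step`) with the preset stored in `attr(, "ground_truth")`.
#' @export
simulate_current_clamp <- function(preset, steps = NULL, noise_sd = 0.2,
                                   seed, sampling_rate = 20000,
                                   baseline = 0.2, step_duration = 1,
                                   tail = 0.1, dt = 0.01, ljp = 0,
                                   cell_id = "sim", group = "") {
  stopifnot(inherits(preset, "neuron_preset"))
  if (sampling_rate < 20000)
    stop("simulate_current_clamp: sampling rate must be >= 20 kHz")
  if (dt > 0.01 + 1e-12)
    stop("simulate_current_clamp: integration step must be <= 0.01 ms")
  steps <- steps %||%
    seq(-20, if (preset$id == "FS") 300 else 200, by = 10)
  if (length(steps) > 1) {
    incs <- unique(round(diff(steps), 9))
    if (length(incs) != 1)
      stop("simulate_current_clamp: step increments must be uniform")
  }
  total <- baseline + step_duration + tail
  vm <- cc_integrate(unclass(preset), as.numeric(steps), baseline,
                     step_duration, total, sampling_rate, dt,
                     settle_ms = 300)
  noise <- if (noise_sd > 0)
    with_seed(seed, matrix(rnorm(length(vm), 0, noise_sd), nrow(vm)))
  else matrix(0, nrow(vm), ncol(vm))
  sweeps <- lapply(seq_along(steps), function(i) {
    sweep_trace(vm[, i] + noise[, i] + ljp, sampling_rate,
                channel = "voltage",
                command = list(type = "step", amplitude = steps[i],
                               onset = baseline, duration = step_duration,
                               unit = "pA"),
                index = i)
  })
  rec <- episodic_recording(
    sweeps,
    protocol = list(mode = "current_step",
                    step_increment = if (length(steps) > 1) diff(steps)[1] else NA,
                    baseline = baseline, step_duration = step_duration,
                    seed = seed),
    cell_id = cell_id, group = group,
    junction_potential = ljp, corrected = (ljp == 0),
    capacitance = preset$c_m,
    access_resistance = 10)
  attr(rec, "ground_truth") <- unclass(preset)
  rec
}
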