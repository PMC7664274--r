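# Voltage-clamp simulators: step families, availability (prepulse)
# protocols, and slow ramps, all built on GHK open-channel flux so the
# permeability analysis can recover the generator truth exactly.

# open-channel current density (pA/pF) at voltage v for a channel truth
truth_flux <- function(truth, v) {
  ghk_current(truth$p_max, v, truth_context(truth))
}

#' Simulate a sodium-current voltage-step family
#'
#' Ideal-voltage-clamp step family from a -120 mV holding potential.
#' Activation is much faster than inactivation (`tau_act` << `tau_inact`,
#' both voltage independent), so the per-step current is
#' `P_max * m_inf(V) * (1 - exp(-t/tau_act)) * h(t) * GHK(V)` with h
#' relaxing from full availability; the peak open probability therefore
#' tracks the steady-state activation curve and a downstream permeability
#' fit recovers the generator's midpoint and slope exactly in the
#' noiseless case.
#'
#' @param truth A [channel_truth()].
#' @param steps Test potentials (mV) within \[-120, +60\]; default -120 to
#'   +30 in 5 mV increments.
#' @param noise_sd Recording noise SD (pA/pF).
#' @param seed RNG seed (required when noise_sd > 0).
#' @param sampling_rate Samples per second.
#' @param pre,pulse Pre-step (holding) and step durations (s).
#' @param capacitance Cell capacitance (pF) recorded in the metadata
#'   (traces are in density units, pA/pF, times this capacitance to give
#'   pA; analysis divides it back out).
#' @param cell_id,group Identity metadata.
#' @return Episodic recording (current channel, protocol `voltage_step`)
#'   with the truth in `attr(, "ground_truth")`.
#' @export
simulate_ina_step_family <- function(truth, steps = seq(-120, 30, by = 5),
                                     noise_sd = 0, seed = NULL,
                                     sampling_rate = 50000,
                                     pre = 0.002, pulse = 0.02,
                                     capacitance = 8, cell_id = "sim",
                                     group = "") {
  stopifnot(inherits(truth, "channel_truth"))
  if (any(steps < -120 | steps > 60))
    stop("simulate_ina_step_family: steps must lie in [-120, +60] mV")
  n_pre <- round(pre * sampling_rate)
  n_pulse <- round(pulse * sampling_rate)
  t_ms <- (seq_len(n_pulse) - 1) / sampling_rate * 1000
  make_sweep <- function(i) {
    v <- steps[i]
    dens <- act_inf(truth, v) * (1 - exp(-t_ms / truth$tau_act)) *
      (inact_inf(truth, v) + (1 - inact_inf(truth, v)) *
         exp(-t_ms / truth$tau_inact)) *
      truth_flux(truth, v)
    i_pa <- c(rep(0, n_pre), dens) * capacitance
    sweep_trace(i_pa, sampling_rate, channel = "current",
                command = list(type = "step", amplitude = v, onset = pre,
                               duration = pulse, unit = "mV",
                               holding = -120),
                index = i)
  }
  sweeps <- lapply(seq_along(steps), make_sweep)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("simulate_ina_step_family: seed required with noise")
    noise <- with_seed(seed, lapply(sweeps, function(s)
      rnorm(length(s$samples), 0, noise_sd * capacitance)))
    for (i in seq_along(sweeps))
      sweeps[[i]]$samples <- sweeps[[i]]$samples + noise[[i]]
  }
  rec <- episodic_recording(
    sweeps,
    protocol = list(mode = "voltage_step", holding = -120,
                    step_increment = if (length(steps) > 1) diff(steps)[1] else NA,
                    onset = pre, pulse = pulse, seed = seed),
    cell_id = cell_id, group = group, corrected = TRUE,
    capacitance = capacitance, access_resistance = 10,
    input_resistance = 2000)
  attr(rec, "ground_truth") <- unclass(truth)
  rec
}

#' Simulate a steady-state availability (prepulse) protocol
#'
#' 500-ms conditioning prepulses (long against `tau_inact`, so availability
#' equilibrates to its steady state) followed by a fixed test pulse near
#' the peak-current voltage. The test-pulse peak is proportional to
#' h_inf(prepulse), giving the generator's inactivation curve exactly.
#'
#' @param truth A [channel_truth()].
#' @param prepulses Conditioning potentials (mV), default -120 to -10 in
#'   10 mV increments.
#' @param test_v Test potential (mV), default -20.
#' @inheritParams simulate_ina_step_family
#' @return Episodic recording (protocol `prepulse`; each sweep's command
#'   carries its `prepulse` level).
#' @export
simulate_ina_availability <- function(truth, prepulses = seq(-120, -10, by = 10),
                                      test_v = -20, noise_sd = 0, seed = NULL,
                                      sampling_rate = 50000, pulse = 0.02,
                                      capacitance = 8, cell_id = "sim",
                                      group = "") {
  stopifnot(inherits(truth, "channel_truth"))
  n_pulse <- round(pulse * sampling_rate)
  t_ms <- (seq_len(n_pulse) - 1) / sampling_rate * 1000
  sweeps <- lapply(seq_along(prepulses), function(i) {
    avail <- inact_inf(truth, prepulses[i])
    dens <- act_inf(truth, test_v) * (1 - exp(-t_ms / truth$tau_act)) *
      avail * exp(-t_ms / truth$tau_inact) * truth_flux(truth, test_v)
    sweep_trace(dens * capacitance, sampling_rate, channel = "current",
                command = list(type = "step", amplitude = test_v, onset = 0,
                               duration = pulse, unit = "mV",
                               prepulse = prepulses[i],
                               prepulse_duration = 0.5),
                index = i)
  })
  if (noise_sd > 0) {
    if (is.null(seed)) stop("simulate_ina_availability: seed required with noise")
    noise <- with_seed(seed, lapply(sweeps, function(s)
      rnorm(length(s$samples), 0, noise_sd * capacitance)))
    for (i in seq_along(sweeps))
      sweeps[[i]]$samples <- sweeps[[i]]$samples + noise[[i]]
  }
  rec <- episodic_recording(
    sweeps,
    protocol = list(mode = "prepulse", test_v = test_v,
                    prepulse_duration = 0.5, seed = seed),
    cell_id = cell_id, group = group, corrected = TRUE,
    capacitance = capacitance, access_resistance = 10,
    input_resistance = 2000)
  attr(rec, "ground_truth") <- unclass(truth)
  rec
}

#' Simulate slow voltage-ramp trials for persistent-current analysis
#'
#' 150 mV / 3 s ramp from -120 mV. The persistent component is the
#' non-inactivating permeability fraction following its activation curve
#' instantaneously (the ramp is slow against channel kinetics):
#' `I(V) = f_pers * P_max * m_inf(V) * GHK(V)`. Optional artificial
#' transient spikes emulate residual unclamped events for testing the
#' excision step.
#'
#' @param truth A [channel_truth()].
#' @param n_trials Number of ramp trials (>= 1); the analysis averages them.
#' @param noise_sd Per-sample noise SD (pA/pF).
#' @param seed RNG seed (required).
#' @param ramp_from,ramp_to,duration Ramp bounds (mV) and duration (s);
#'   bounds must span `ramp_to - ramp_from = 50 mV/s * duration` (checked).
#' @param n_transients Artificial transient spikes injected per trial at
#'   random times (amplitude ~ 30x the persistent density, 2 ms wide).
#' @param sampling_rate Samples per second.
#' @param capacitance Cell capacitance (pF).
#' @param cell_id,group Identity metadata.
#' @return List of [sweep_trace()] ramp trials with the truth (including
#'   the analytic density at -20 mV) in `attr(, "ground_truth")`.
#' @export
simulate_ramp <- function(truth, n_trials = 4, noise_sd = 0.05, seed,
                          ramp_from = -120, ramp_to = 30, duration = 3,
                          n_transients = 0, sampling_rate = 20000,
                          capacitance = 20, cell_id = "sim", group = "") {
  stopifnot(inherits(truth, "channel_truth"))
  if (n_trials < 1) stop("simulate_ramp: n_trials must be >= 1")
  rate <- (ramp_to - ramp_from) / duration
  if (abs(rate - 50) > 1e-9)
    stop("simulate_ramp: ramp bounds inconsistent with a 150 mV / 3 s ramp")
  n <- round(duration * sampling_rate)
  v <- ramp_from + (seq_len(n) - 1) / sampling_rate * rate
  dens <- truth$persistent_fraction * truth$p_max *
    act_inf(truth, v) * ghk_current(1, v, truth_context(truth))
  trials <- with_seed(seed, lapply(seq_len(n_trials), function(tr) {
    x <- dens + rnorm(n, 0, noise_sd)
    if (n_transients > 0) {
      at <- sample(seq(0.2 * n, 0.95 * n), n_transients)
      width <- round(0.002 * sampling_rate)
      for (a in at) {
        idx <- a:min(a + width, n)
        shape <- exp(-((idx - a) / (width / 4))^2)
        x[idx] <- x[idx] - 30 * max(abs(dens)) * shape
      }
    }
    sweep_trace(x * capacitance, sampling_rate, channel = "current",
                command = list(type = "ramp", from = ramp_from, to = ramp_to,
                               onset = 0, duration = duration),
                index = tr)
  }))
  truth_at_m20 <- truth$persistent_fraction * truth$p_max *
    act_inf(truth, -20) * ghk_current(1, -20, truth_context(truth))
  attr(trials, "ground_truth") <- c(unclass(truth),
                                    list(density_at_m20 = truth_at_m20,
                                         capacitance = capacitance,
                                         noise_sd = noise_sd))
  trials
}
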