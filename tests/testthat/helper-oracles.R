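# Independent oracles and small fixture builders used across the suite.

# Brute-force spike counter: local maxima above 0 mV, counted as separate
# spikes only when separated by a dip below -20 mV.
brute_force_spike_count <- function(v) {
  above <- v > 0
  if (!any(above)) return(0L)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  count <- 1L
  if (length(runs) > 1) {
    for (j in 2:length(runs)) {
      gap <- v[ends[runs[j - 1]]:starts[runs[j]]]
      if (min(gap) < -20) count <- count + 1L
    }
  }
  count
}

# Textbook log-rank oracle: 2x2 table per distinct death time with
# hypergeometric variance.
logrank_oracle <- function(day, event, group) {
  g1 <- group == unique(group)[1]
  times <- sort(unique(day[event == 1]))
  o <- 0; e <- 0; v <- 0
  for (t in times) {
    at1 <- sum(day >= t & g1); at2 <- sum(day >= t & !g1)
    d1 <- sum(day == t & event == 1 & g1)
    d2 <- sum(day == t & event == 1 & !g1)
    n <- at1 + at2; d <- d1 + d2
    if (n < 2 || d == 0) next
    o <- o + d1
    e <- e + d * at1 / n
    v <- v + d * (at1 / n) * (at2 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}

# Brute-force two-sample KS statistic: max ECDF gap over the pooled support
ks_oracle <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  fa <- vapply(xs, function(x) mean(a <= x), numeric(1))
  fb <- vapply(xs, function(x) mean(b <= x), numeric(1))
  max(abs(fa - fb))
}

# Numeric kinetic-integration oracle for the voltage-step simulator: Euler
# integration of dm/dt = (m_inf - m)/tau_a and dh/dt = (h_inf - h)/tau_i
# from m = 0, h = 1, returning the signed peak current density.
kinetic_peak_oracle <- function(truth, v, t_end_ms = 20, dt = 5e-4) {
  ctx <- truth_context(truth)
  minf <- 1 / (1 + exp((truth$act_vhalf - v) / truth$act_k))
  hinf <- 1 / (1 + exp((v - truth$inact_vhalf) / truth$inact_k))
  flux <- ghk_current(truth$p_max, v, ctx)
  m <- 0; h <- 1
  peak <- 0
  for (i in seq_len(round(t_end_ms / dt))) {
    m <- m + dt * (minf - m) / truth$tau_act
    h <- h + dt * (hinf - h) / truth$tau_inact
    cur <- m * h * flux
    if (abs(cur) > abs(peak)) peak <- cur
  }
  peak
}

# Synthetic sweep with n triangular spikes (1 ms rise / 1 ms fall from
# -70 mV to +30 mV), evenly spaced within the step epoch.
make_spike_sweep <- function(n_spikes, amp_pa, sampling_rate = 20000,
                             baseline = 0.1, step_dur = 1, tail = 0.1,
                             peak_mv = 30, base_mv = -70) {
  n <- round((baseline + step_dur + tail) * sampling_rate)
  v <- rep(base_mv, n)
  if (n_spikes > 0) {
    at <- baseline + step_dur * (seq_len(n_spikes) - 0.5) / n_spikes
    half <- round(0.001 * sampling_rate)           # 1 ms rise and fall
    for (t0 in at) {
      i0 <- round(t0 * sampling_rate)
      up <- seq(0, 1, length.out = half + 1)
      v[i0:(i0 + half)] <- base_mv + up * (peak_mv - base_mv)
      v[(i0 + half):(i0 + 2 * half)] <- peak_mv - up * (peak_mv - base_mv)
    }
  }
  sweep_trace(v, sampling_rate, channel = "voltage",
              command = list(type = "step", amplitude = amp_pa,
                             onset = baseline, duration = step_dur,
                             unit = "pA"))
}

# Current-step recording assembled from artificial spike sweeps, one per
# element of `counts` (names = injected pA).
make_count_recording <- function(counts, ...) {
  amps <- as.numeric(names(counts))
  sweeps <- lapply(seq_along(amps), function(i) {
    s <- make_spike_sweep(counts[[i]], amps[i], ...)
    s$index <- i
    s
  })
  episodic_recording(sweeps, protocol = list(mode = "current_step",
                                             step_increment = diff(amps)[1]),
                     corrected = TRUE, capacitance = 20,
                     access_resistance = 10)
}
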