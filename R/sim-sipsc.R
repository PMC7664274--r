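# Spontaneous-IPSC trace simulator: Poisson onsets, truncated-Gaussian
# amplitudes, biexponential kernel, additive Gaussian baseline noise.

# biexponential kernel normalized to unit peak; returns a numeric vector
# covering ~8 decay constants
sipsc_kernel <- function(rise, decay, sampling_rate) {
  n <- max(2L, ceiling(8 * decay / 1000 * sampling_rate))
  t_ms <- (seq_len(n) - 1) / sampling_rate * 1000
  k <- exp(-t_ms / decay) - exp(-t_ms / rise)
  k / max(k)
}

#' Simulate event times and amplitudes for one sIPSC cell
#'
#' Ground-truth generator: Poisson event onsets at the stated rate over the
#' stated duration, amplitudes from a Gaussian truncated at zero. Used both
#' to render full traces ([simulate_sipsc()]) and on its own for
#' cohort-level statistics where trace rendering is unnecessary.
#'
#' @param truth A [synaptic_truth()].
#' @param seed RNG seed (required).
#' @return Data frame with columns `onset` (s, strictly increasing) and
#'   `amplitude` (pA, > 0).
#' @export
simulate_sipsc_events <- function(truth, seed) {
  stopifnot(inherits(truth, "synaptic_truth"))
  with_seed(seed, {
    n <- rpois(1, truth$rate * truth$duration)
    if (n == 0) return(data.frame(onset = numeric(0), amplitude = numeric(0)))
    onset <- sort(runif(n, 0, truth$duration))
    amplitude <- rnorm(n, truth$amp_mean, truth$amp_sd)
    amplitude <- pmax(amplitude, 0.5)   # physical floor, avoids negatives
    data.frame(onset = onset, amplitude = amplitude)
  })
}

#' Simulate a gap-free sIPSC recording
#'
#' Renders a full current trace: each ground-truth event contributes its
#' amplitude times a unit-peak biexponential kernel, with inward (negative)
#' polarity as recorded at -80 mV under a high-chloride internal; Gaussian
#' baseline noise is added on top.
#'
#' @param truth A [synaptic_truth()].
#' @param seed RNG seed (required).
#' @param sampling_rate Samples per second (default 20 kHz).
#' @return List with `sweep` (a gap-free current [sweep_trace()]) and
#'   `events` (the ground-truth onset/amplitude data frame).
#' @export
simulate_sipsc <- function(truth, seed, sampling_rate = 20000) {
  stopifnot(inherits(truth, "synaptic_truth"))
  events <- simulate_sipsc_events(truth, seed)
  n <- round(truth$duration * sampling_rate)
  x <- numeric(n)
  if (nrow(events) > 0) {
    k <- sipsc_kernel(truth$rise, truth$decay, sampling_rate)
    for (i in seq_len(nrow(events))) {
      i0 <- 1 + floor(events$onset[i] * sampling_rate)
      idx <- i0:min(i0 + length(k) - 1, n)
      x[idx] <- x[idx] - events$amplitude[i] * k[seq_along(idx)]
    }
  }
  if (truth$noise_sd > 0)
    x <- x + with_seed(seed + 1L, rnorm(n, 0, truth$noise_sd))
  sw <- sweep_trace(x, sampling_rate, channel = "current",
                    command = list(type = "gapfree"))
  list(sweep = sw, events = events)
}
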