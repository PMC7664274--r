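# Ground-truth parameter containers for the bundled simulators.

#' Seed-scoped RNG helper: run code under a given seed without disturbing
#' the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) stop("a seed is required")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Single-compartment neuron preset
#'
#' Parameters of the conductance-based model behind
#' [simulate_current_clamp()]: leak, transient sodium (instantaneous cubic
#' activation with inactivation), a non-inactivating persistent sodium
#' fraction, and a delayed-rectifier potassium current. Kinetic tempo
#' factors (`phi_h`, `phi_n`) set how fast inactivation and the rectifier
#' move: large values give the narrow spikes and deep fast
#' afterhyperpolarization of fast-spiking (FS, parvalbumin-positive)
#' interneurons, smaller values the broader spikes of regular-spiking (RS)
#' pyramidal cells.
#'
#' The four named presets are calibrated to the passive and spike-shape
#' ranges of the cortical populations the demo study emulates (FS
#' interneurons; layer-5, layer-6 and subicular pyramidal cells). The
#' genotype factor `g_scale` multiplies both sodium conductances
#' (1 = wild-type; the demo null cohorts use 0.65 for FS and 0.60 for
#' layer 6, which also lowers capacitance and leak per its preset).
#'
#' @param id One of `"FS"`, `"RS-layer5"`, `"RS-layer6"`, `"RS-subiculum"`.
#' @param g_scale Sodium-conductance scale, 0 < g_scale <= 1.
#' @param genotype `"wt"` or `"null"`. For `"null"`, applies the preset's
#'   calibrated genotype contrast (g_scale and, for RS-layer6, the passive
#'   shifts: ~25% lower capacitance, lower leak, depolarized resting
#'   potential). Explicit `g_scale` overrides the genotype default.
#' @param ... Named overrides for any model parameter (see Value).
#' @return Object of class `neuron_preset`: list with `id`, `g_scale`,
#'   `c_m` (pF), `g_leak` (nS), `e_leak` (mV), `g_na` (nS), `e_na` (mV),
#'   `persistent_fraction`, `g_k` (nS), `e_k` (mV), `phi_h`, `phi_n`,
#'   `na_shift` (mV, depolarizing shift of the Na voltage dependence).
#' @export
neuron_preset <- function(id = c("FS", "RS-layer5", "RS-layer6", "RS-subiculum"),
                          g_scale = NULL, genotype = c("wt", "null"), ...) {
  id <- match.arg(id)
  genotype <- match.arg(genotype)
  base <- switch(id,
    "FS" = list(c_m = 22, g_leak = 4.7, e_leak = -71.2, g_na = 700,
                e_na = 55, persistent_fraction = 0.004, g_k = 100,
                e_k = -90, phi_h = 3, phi_n = 5, na_shift = 6),
    "RS-layer5" = list(c_m = 52, g_leak = 10.9, e_leak = -84.7, g_na = 1700,
                       e_na = 55, persistent_fraction = 0.006, g_k = 360,
                       e_k = -95, phi_h = 1, phi_n = 1, na_shift = -8),
    "RS-layer6" = list(c_m = 19.5, g_leak = 2.2, e_leak = -81.7, g_na = 250,
                       e_na = 55, persistent_fraction = 0.006, g_k = 30,
                       e_k = -95, phi_h = 0.8, phi_n = 1, na_shift = 5),
    "RS-subiculum" = list(c_m = 33, g_leak = 7.4, e_leak = -78.5, g_na = 1150,
                          e_na = 55, persistent_fraction = 0.006, g_k = 240,
                          e_k = -95, phi_h = 1, phi_n = 1, na_shift = -4))
  default_scale <- 1
  if (genotype == "null") {
    default_scale <- switch(id, "FS" = 0.65, "RS-layer6" = 0.60, 0.65)
    if (id == "RS-layer6") {
      base$c_m <- base$c_m * 0.75       # 19.5 -> 14.6 pF
      base$g_leak <- base$g_leak * 0.69 # input resistance 462 -> ~670 MOhm
      base$e_leak <- base$e_leak + 4.9  # depolarized rest
    }
  }
  g_scale <- g_scale %||% default_scale
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad)) stop("neuron_preset: unknown parameters: ",
                        paste(bad, collapse = ", "))
  base[names(over)] <- over
  p <- c(list(id = id, g_scale = g_scale), base)
  if (!(p$g_scale > 0 && p$g_scale <= 1))
    stop("neuron_preset: g_scale must be in (0, 1]")
  if (p$c_m <= 0) stop("neuron_preset: capacitance must be > 0")
  if (any(unlist(p[c("g_leak", "g_na", "g_k")]) < 0))
    stop("neuron_preset: conductances must be >= 0")
  structure(p, class = "neuron_preset")
}

#' Sodium-channel ground truth for the voltage-clamp simulators
#'
#' @param p_max Maximal permeability (cm/s).
#' @param act_vhalf,act_k Activation midpoint and slope (mV, k > 0).
#' @param inact_vhalf,inact_k Steady-state inactivation midpoint and slope
#'   (mV, k > 0).
#' @param persistent_fraction Fraction of the peak permeability that does
#'   not inactivate (measured on slow ramps).
#' @param conc_in,conc_out Internal / external Na concentration (mM);
#'   defaults match a reduced-sodium recording configuration (10 / 30 mM).
#' @param temperature Absolute temperature (K).
#' @param tau_act,tau_inact Activation / inactivation time constants (ms),
#'   voltage independent; activation is much faster than inactivation so
#'   the peak open probability tracks the steady-state activation curve.
#' @return Object of class `channel_truth`.
#' @export
channel_truth <- function(p_max = 1e-4, act_vhalf = -35.45, act_k = 6.47,
                          inact_vhalf = -58.56, inact_k = 5.30,
                          persistent_fraction = 0.01,
                          conc_in = 10, conc_out = 30, temperature = 295,
                          tau_act = 0.15, tau_inact = 5) {
  if (act_k <= 0 || inact_k <= 0)
    stop("channel_truth: slope factors must be > 0")
  if (conc_in <= 0 || conc_out <= 0)
    stop("channel_truth: concentrations must be > 0")
  if (p_max < 0) stop("channel_truth: p_max must be >= 0")
  structure(list(p_max = p_max, act_vhalf = act_vhalf, act_k = act_k,
                 inact_vhalf = inact_vhalf, inact_k = inact_k,
                 persistent_fraction = persistent_fraction,
                 conc_in = conc_in, conc_out = conc_out,
                 temperature = temperature,
                 tau_act = tau_act, tau_inact = tau_inact),
            class = "channel_truth")
}

#' GHK context of a channel truth
#' @param truth A [channel_truth()].
#' @return The matching [ghk_context()].
#' @export
truth_context <- function(truth) {
  stopifnot(inherits(truth, "channel_truth"))
  ghk_context(z = 1, conc_in = truth$conc_in, conc_out = truth$conc_out,
              temperature = truth$temperature)
}

# Boltzmann steady states of a channel truth
act_inf <- function(truth, v) 1 / (1 + exp((truth$act_vhalf - v) / truth$act_k))
inact_inf <- function(truth, v) 1 / (1 + exp((v - truth$inact_vhalf) / truth$inact_k))

#' Spontaneous-IPSC ground truth
#'
#' @param rate Event rate (Hz, >= 0; Poisson onsets).
#' @param amp_mean,amp_sd Amplitude distribution (pA), truncated at 0.
#' @param rise,decay Biexponential kernel time constants (ms), decay > rise.
#' @param noise_sd Baseline Gaussian noise SD (pA).
#' @param duration Trace duration (s).
#' @return Object of class `synaptic_truth`.
#' @export
synaptic_truth <- function(rate = 3.81, amp_mean = 35, amp_sd = 12,
                           rise = 0.8, decay = 8, noise_sd = 2,
                           duration = 300) {
  if (rate < 0) stop("synaptic_truth: rate must be >= 0")
  if (!(decay > rise && rise > 0))
    stop("synaptic_truth: need decay > rise > 0")
  if (duration <= 0) stop("synaptic_truth: duration must be > 0")
  structure(list(rate = rate, amp_mean = amp_mean, amp_sd = amp_sd,
                 rise = rise, decay = decay, noise_sd = noise_sd,
                 duration = duration),
            class = "synaptic_truth")
}
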