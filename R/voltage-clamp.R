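# Voltage-clamp analysis: peak I-V extraction, GHK-permeability activation
# curves, availability curves, persistent-current ramp analysis, and
# nucleated-patch QC.

#' Peak current-voltage relationship of a step family
#'
#' For each test potential, takes the signed inward extremum of the current
#' within a detection window after step onset (default 0.2-10 ms, skipping
#' the capacitive transient) and divides by the cell capacitance to give
#' current density (pA/pF).
#'
#' @param recording A voltage-step [episodic_recording()] (current channel)
#'   with capacitance > 0.
#' @param window Detection window after step onset, c(start, end) in s.
#' @param reference_voltage Step at which the summary density is reported
#'   (-25 mV for dissociated-cell families, -20 mV for nucleated patches).
#'   Must be present in the protocol.
#' @return Object of class `iv_curve`: data frame columns `voltage` (mV),
#'   `density` (pA/pF) in `$iv`, plus `capacitance`, `reference_voltage`,
#'   `reference_density`.
#' @export
peak_iv <- function(recording, window = c(2e-4, 1e-2),
                    reference_voltage = -25) {
  stopifnot(inherits(recording, "ck_recording"))
  if (is.na(recording$capacitance) || recording$capacitance <= 0)
    stop("peak_iv: recording needs a positive capacitance")
  amps <- command_levels(recording$sweeps)
  if (!reference_voltage %in% amps)
    stop(sprintf("peak_iv: reference voltage %g mV absent from the protocol",
                 reference_voltage))
  dens <- vapply(recording$sweeps, function(s) {
    sr <- s$sampling_rate
    onset <- s$command$onset
    i0 <- max(1, round((onset + window[1]) * sr))
    i1 <- min(length(s$samples), round((onset + window[2]) * sr))
    seg <- s$samples[i0:i1]
    seg[which.max(abs(seg))] / recording$capacitance
  }, numeric(1))
  structure(list(iv = data.frame(voltage = amps, density = dens),
                 capacitance = recording$capacitance,
                 reference_voltage = reference_voltage,
                 reference_density = dens[match(reference_voltage, amps)]),
            class = "iv_curve")
}

#' @export
print.iv_curve <- function(x, ...) {
  cat(sprintf("<iv_curve> %d steps, peak density %.1f pA/pF at %g mV\n",
              nrow(x$iv), x$reference_density, x$reference_voltage))
  invisible(x)
}

#' GHK-permeability activation curve from a peak I-V
#'
#' Converts peak current densities to permeabilities through the
#' constant-field equation, normalizes to the maximum, and fits an
#' activation Boltzmann. Working on permeability rather than chord
#' conductance makes the curve independent of the driving-force shape and
#' invariant to overall density scaling. Voltages at or above the reversal
#' potential (and those below `v_min`, where the channel is closed and the
#' permeability ratio is noise) are excluded from the fit.
#'
#' @param iv An [peak_iv()] result.
#' @param ctx The recording's [ghk_context()].
#' @param v_min Lowest voltage included in the fit (default -80 mV).
#' @return List: `curve` (data frame voltage / permeability / normalized)
#'   and `fit` (a [fit_boltzmann()] activation fit).
#' @export
activation_curve <- function(iv, ctx, v_min = -80) {
  stopifnot(inherits(iv, "iv_curve"), inherits(ctx, "ghk_context"))
  erev <- ghk_reversal(ctx)
  keep <- iv$iv$voltage >= v_min & iv$iv$voltage < erev - 5
  v <- iv$iv$voltage[keep]
  perm <- ghk_permeability(iv$iv$density[keep], v, ctx)
  pmax <- max(perm)
  if (pmax <= 0) stop("activation_curve: no measurable permeability")
  y <- perm / pmax
  list(curve = data.frame(voltage = v, permeability = perm, normalized = y),
       fit = fit_boltzmann(v, y, direction = "activation"))
}

#' Steady-state availability curve from a prepulse protocol
#'
#' Normalizes test-pulse peak currents to the maximum across conditioning
#' prepulses and fits an inactivation Boltzmann.
#'
#' @param recording A prepulse [episodic_recording()] from
#'   [simulate_ina_availability()] or equivalent (each sweep's command
#'   carries its `prepulse` level).
#' @param window Peak-detection window after test-pulse onset (s).
#' @return List: `curve` (data frame prepulse / peak / normalized) and
#'   `fit` (inactivation [fit_boltzmann()]).
#' @export
availability_curve <- function(recording, window = c(2e-4, 1e-2)) {
  stopifnot(inherits(recording, "ck_recording"))
  pre <- vapply(recording$sweeps, function(s)
    s$command$prepulse %||% NA_real_, numeric(1))
  if (anyNA(pre))
    stop("availability_curve: sweeps lack prepulse levels")
  peaks <- vapply(recording$sweeps, function(s) {
    sr <- s$sampling_rate
    onset <- s$command$onset
    i0 <- max(1, round((onset + window[1]) * sr))
    i1 <- min(length(s$samples), round((onset + window[2]) * sr))
    seg <- s$samples[i0:i1]
    seg[which.max(abs(seg))]
  }, numeric(1))
  mx <- max(abs(peaks))
  if (mx < .Machine$double.eps^0.5)
    stop("availability_curve: all test-pulse peaks are ~0; cannot normalize")
  y <- abs(peaks) / mx
  list(curve = data.frame(prepulse = pre, peak = peaks, normalized = y),
       fit = fit_boltzmann(pre, y, direction = "inactivation"))
}

#' Persistent-current ramp analysis
#'
#' Averages slow-ramp trials after excising residual transient spikes:
#' samples where |dI/dt| exceeds `transient_k` times the robust SD (MAD) of
#' the trial's derivative are flagged, flagged runs are expanded to the
#' local baseline, and the gap is bridged by linear interpolation. The
#' persistent density is read at -20 mV on the averaged trace (mean over
#' +/- 1 mV of command voltage), and an activation curve is derived from
#' the averaged ramp by GHK normalization over the rising limb.
#'
#' @param trials List of ramp [sweep_trace()]s (equal length, same ramp
#'   command), e.g. from [simulate_ramp()].
#' @param capacitance Cell capacitance (pF) for density scaling.
#' @param ctx Optional [ghk_context()]; needed for the ramp-derived
#'   activation fit (skipped when NULL).
#' @param transient_k Excision criterion: multiples of the robust
#'   derivative SD (default 8).
#' @param max_excised Maximal excisable fraction of the ramp (default 0.2);
#'   beyond it the trace is declared unusable.
#' @return Object of class `ramp_result`: `average` (data frame `voltage`,
#'   `density`), `density_at_m20` (pA/pF), `n_trials`, `n_excised`
#'   (samples excised per trial), `activation_fit` (or NULL).
#' @export
analyze_ramp <- function(trials, capacitance, ctx = NULL, transient_k = 8,
                         max_excised = 0.2) {
  if (length(trials) < 1) stop("analyze_ramp: need at least one ramp trial")
  stopifnot(all(vapply(trials, inherits, logical(1), "ck_sweep")))
  cmd <- trials[[1]]$command
  if (cmd$type != "ramp") stop("analyze_ramp: sweeps are not ramp trials")
  n <- length(trials[[1]]$samples)
  v <- cmd$from + (seq_len(n) - 1) / n * (cmd$to - cmd$from)
  n_excised <- integer(length(trials))
  cleaned <- lapply(seq_along(trials), function(k) {
    x <- trials[[k]]$samples
    dx <- c(0, diff(x))
    s <- stats::mad(dx)
    if (s == 0) return(x)
    bad <- abs(dx) > transient_k * s
    # expand flagged runs by 1 ms on both sides to reach local baseline
    if (any(bad)) {
      pad <- round(0.001 * trials[[k]]$sampling_rate)
      idx <- which(bad)
      for (i in idx) bad[max(1, i - pad):min(n, i + pad)] <- TRUE
      n_excised[k] <<- sum(bad)
      if (mean(bad) > max_excised)
        stop(sprintf(paste0("analyze_ramp: transient span %.0f%% of trial %d",
                            " exceeds %.0f%%; trace unusable"),
                     100 * mean(bad), k, 100 * max_excised))
      good <- which(!bad)
      x[bad] <- approx(good, x[good], xout = which(bad), rule = 2)$y
    }
    x
  })
  avg <- Reduce(`+`, cleaned) / length(cleaned)
  dens <- avg / capacitance
  at <- abs(v + 20) <= 1
  d20 <- mean(dens[at])
  fit <- NULL
  if (!is.null(ctx)) {
    erev <- ghk_reversal(ctx)
    keep <- v >= -80 & v < erev - 5
    # decimate for the fit; the ramp is slow so this loses nothing
    kk <- which(keep)[seq(1, sum(keep), length.out = min(200, sum(keep)))]
    perm <- ghk_permeability(dens[kk], v[kk], ctx)
    pm <- max(perm)
    if (pm > 0)
      fit <- fit_boltzmann(v[kk], perm / pm, direction = "activation")
  }
  structure(list(average = data.frame(voltage = v, density = dens),
                 density_at_m20 = d20, n_trials = length(trials),
                 n_excised = n_excised, activation_fit = fit),
            class = "ramp_result")
}

#' Nucleated-patch quality control
#'
#' A patch fails if its access resistance exceeds 20 MOhm or its input
#' resistance is below 1 GOhm.
#'
#' @param recording An [episodic_recording()] with `access_resistance`
#'   (MOhm) and `input_resistance` (MOhm) populated.
#' @return List `pass` (logical) and `reason` ("" | "Ra" | "Rin" | "Ra+Rin").
#' @export
nucleated_patch_qc <- function(recording) {
  stopifnot(inherits(recording, "ck_recording"))
  ra <- recording$access_resistance
  rin <- recording$input_resistance
  if (is.na(ra) || is.na(rin))
    stop("nucleated_patch_qc: access and input resistance must be present")
  reason <- character(0)
  if (ra > 20) reason <- c(reason, "Ra")
  if (rin < 1000) reason <- c(reason, "Rin")
  list(pass = length(reason) == 0, reason = paste(reason, collapse = "+"))
}
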